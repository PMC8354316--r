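# Metric-level band-power injection: build a band_power object directly
# from an electrodes x frames matrix, bypassing the spectral stage.
bp_from_matrix <- function(m, subject = "s01", stimulus = "stim01",
                           electrodes = c("C3", "Cz", "C4"),
                           band = "alpha", frame_valid = NULL, fs = 256) {
  stopifnot(nrow(m) == length(electrodes))
  structure(list(
    subject_id = subject, stimulus_id = stimulus, fs = fs,
    channels = electrodes, bands = band,
    frame_times = 0.25 + 0.25 * (seq_len(ncol(m)) - 1),
    power = array(m, dim = c(nrow(m), 1, ncol(m)),
                  dimnames = list(electrodes, band, NULL)),
    frame_valid = frame_valid %||% rep(TRUE, ncol(m))
  ), class = "band_power")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force evaluation of the synchrony definition: a naive
# triple loop over frames and ordered subject pairs, correlating flattened
# electrode-by-frame windows.
naive_synchrony <- function(mats, hw = 2, scale = 100) {
  n_sub <- length(mats)
  n_frames <- ncol(mats[[1]])
  frame_vals <- numeric(0)
  for (t in (hw + 1):(n_frames - hw)) {
    rs <- numeric(0)
    for (i in seq_len(n_sub)) for (j in seq_len(n_sub)) if (j != i) {
      xi <- as.vector(mats[[i]][, (t - hw):(t + hw)])
      xj <- as.vector(mats[[j]][, (t - hw):(t + hw)])
      rs <- c(rs, abs(stats::cor(xi, xj)))
    }
    frame_vals <- c(frame_vals, sum(rs) / (n_sub * (n_sub - 1)))
  }
  scale * mean(frame_vals)
}

# closed-form null expectation of |r| for n iid Gaussian pairs:
# r^2 ~ Beta(1/2, (n-2)/2)  =>  E|r| = (1/(k+1)) / B(1/2, (n-2)/2), k=(n-4)/2
expected_abs_r_null <- function(n) {
  k <- (n - 4) / 2
  (1 / (k + 1)) / beta(0.5, (n - 2) / 2)
}

# single-channel recording holding a pure sinusoid (or DC) in microvolts
sine_recording <- function(freq, duration_s = 10, fs = 256, amp = 1,
                           channel = "Cz") {
  t <- (seq_len(duration_s * fs) - 1) / fs
  x <- if (freq == 0) rep(amp, length(t)) else amp * sin(2 * pi * freq * t)
  eeg_recording(matrix(x, 1), fs, channel, "s01", "stim01")
}

# small simulated study shared across IO tests
small_sim <- function(seed = 5, n_subjects = 2, n_stimuli = 3,
                      duration_s = 2) {
  simulate_eeg(study_config(n_subjects = n_subjects, n_stimuli = n_stimuli,
                            duration_s = duration_s, seed = seed))
}
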