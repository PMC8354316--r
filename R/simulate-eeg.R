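# Signal-level building blocks ------------------------------------------

# 1/f-amplitude ("pink") noise by spectral shaping of white noise,
# standardised to unit SD. DC is zeroed so the series is mean-free.
pink_noise <- function(n) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)             # cycles per record; symmetric in +/- freq
  h <- ifelse(f > 0, 1 / sqrt(f), 0)
  y <- Re(stats::fft(X * h, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Bursty non-negative amplitude envelope: band-limited Gaussian noise
# mapped through exp() (log-normal bursts, the usual picture of waxing
# and waning alpha), normalised to unit mean so it acts as a pure
# amplitude modulation. The band is kept away from DC (`lo_hz`) so the
# envelope genuinely fluctuates at the 250 ms band-power frame scale
# instead of drifting (a drifting envelope makes short windows look like
# monotone ramps, which correlate spuriously across subjects), and the
# log-normal contrast (`log_sd`) makes envelope-driven power fluctuations
# dominate the band-power variance, so shared-envelope coupling is
# visible in windowed correlations.
smooth_envelope <- function(n, fs, cut_hz = 2, lo_hz = 0.5, log_sd = 1) {
  bf <- signal::butter(2, c(lo_hz, cut_hz) / (fs / 2), type = "pass")
  g <- signal::filtfilt(bf, stats::rnorm(n))
  e <- exp(log_sd * g / stats::sd(g))
  e / mean(e)
}

# Generative study --------------------------------------------------------

#' Simulate a multi-subject EEG listening study
#'
#' Generates one [eeg_recording()] per (subject, stimulus) under a known
#' ground truth. Every channel carries a mixture of a stimulus-locked alpha
#' component (a smooth random envelope, identical across subjects, carried
#' on a 10 Hz oscillation with a subject-specific phase), an idiosyncratic
#' alpha oscillation at a subject-specific frequency in 8-12 Hz, pink (1/f)
#' background and broadband white noise, all in microvolts. The per-stimulus
#' coupling weight `shared_weight` moves alpha power between the fully
#' idiosyncratic (0) and fully shared (1) regimes through energy-preserving
#' amplitude weights `sqrt(w)` and `sqrt(1 - w)`, so total alpha power -
#' and with it the temporal statistics that set the synchrony null level -
#' does not depend on the coupling.
#'
#' Frontal lateralisation: the alpha amplitude at F4 is scaled by
#' `exp(+valence/2 + offset)` and at F3 by `exp(-valence/2 + offset)` with a
#' per-subject offset, so expected frontal alpha asymmetry
#' (ln alpha-power F4 - ln alpha-power F3) increases with stimulus valence.
#'
#' High-amplitude artifacts (square pulses of 450-800 uV lasting 100-300 ms,
#' unambiguously beyond the 400 uV rejection gate) are injected on a random
#' channel at `artifact_rate` per minute.
#'
#' The result is a pure function of `(config, config$seed)`: rerunning with
#' the same configuration reproduces every sample bit-exactly, and the
#' number of random draws does not depend on the values of `shared_weight`
#' or `valence`, so runs that differ only in those fields stay paired.
#'
#' @param config A [study_config()].
#' @return A list with elements
#'   * `recordings`: tibble with columns `subject_id`, `stimulus_id` and a
#'     list-column `recording` of [eeg_recording()] objects;
#'   * `truth`: a `ground_truth` list with per-stimulus parameters
#'     (including the noise-free synchrony proxy and expected log-streams),
#'     per-subject parameters, and injected artifact locations.
#' @export
#' @examples
#' sim <- simulate_eeg(study_config(n_subjects = 3, n_stimuli = 2,
#'                                  duration_s = 2, seed = 7))
#' sim$recordings
simulate_eeg <- function(config) {
  cfg <- validate_study_config(config)
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1L) / cfg$fs
  nS <- cfg$n_subjects; nK <- cfg$n_stimuli
  subj_ids <- sprintf("s%02d", seq_len(nS))
  stim_ids <- sprintf("stim%02d", seq_len(nK))

  # stimulus-level parameters (drawn only where unspecified; the draw count
  # never depends on supplied values)
  w <- cfg$shared_weight %||% stats::runif(nK, 0.2, 0.8)
  valence <- cfg$valence %||% stats::rnorm(nK, 0, 0.5)
  artist <- cfg$artist_label %||%
    rep(c("artist_rnb", "artist_pop"),
        times = c(ceiling(nK * 13 / 24), nK - ceiling(nK * 13 / 24)))
  single <- cfg$single_flag %||% as.logical(stats::ave(
    rep(1, nK), artist, FUN = function(z) seq_along(z) <= min(4, length(z))))

  # shared stimulus-locked envelopes (identical across subjects)
  A_shared <- lapply(seq_len(nK), function(k) smooth_envelope(n, cfg$fs))

  # subject-level parameters
  phi <- stats::runif(nS, 0, 2 * pi)
  f_subj <- stats::runif(nS, 8, 12)
  faa_offset <- stats::rnorm(nS, 0, 0.1)

  iF3 <- match("F3", cfg$channels)
  iF4 <- match("F4", cfg$channels)
  nC <- length(cfg$channels)

  rows <- vector("list", nS * nK)
  artifacts <- list()
  r <- 0L
  for (i in seq_len(nS)) {
    carrier_shared <- sin(2 * pi * 10 * t + phi[i])
    for (k in seq_len(nK)) {
      phi_idio <- stats::runif(1, 0, 2 * pi)
      A_idio <- smooth_envelope(n, cfg$fs)
      carrier_idio <- sin(2 * pi * f_subj[i] * t + phi_idio)
      # energy-preserving mixing: the coupling weight moves alpha power
      # between the shared and idiosyncratic components without changing
      # the total alpha power, so the synchrony null level is stable in w
      alpha <- cfg$alpha_uv *
        (sqrt(w[k]) * A_shared[[k]] * carrier_shared +
           sqrt(1 - w[k]) * A_idio * carrier_idio)
      X <- matrix(0, nC, n)
      for (c in seq_len(nC)) {
        scale_c <- if (!is.na(iF3) && c == iF3) {
          exp(-valence[k] / 2 + faa_offset[i])
        } else if (!is.na(iF4) && c == iF4) {
          exp(valence[k] / 2 + faa_offset[i])
        } else 1
        X[c, ] <- scale_c * alpha +
          cfg$pink_uv * pink_noise(n) +
          cfg$white_uv * stats::rnorm(n)
      }
      # artifact injection: square pulses > 400 uV on one random channel
      n_art <- stats::rpois(1, cfg$artifact_rate * cfg$duration_s / 60)
      if (n_art > 0) {
        for (a in seq_len(n_art)) {
          width <- round(stats::runif(1, 0.1, 0.3) * cfg$fs)
          start <- sample.int(max(1L, n - width), 1)
          amp <- sample(c(-1, 1), 1) * stats::runif(1, 450, 800)
          ch <- sample.int(nC, 1)
          idx <- start:min(n, start + width - 1L)
          X[ch, idx] <- X[ch, idx] + amp
          artifacts[[length(artifacts) + 1L]] <- tibble::tibble(
            subject_id = subj_ids[i], stimulus_id = stim_ids[k],
            channel = cfg$channels[ch],
            start_index = start - 1L, end_index = idx[length(idx)] - 1L,
            amplitude_uv = amp)
        }
      }
      r <- r + 1L
      rows[[r]] <- tibble::tibble(
        subject_id = subj_ids[i], stimulus_id = stim_ids[k],
        recording = list(eeg_recording(X, cfg$fs, cfg$channels,
                                       subj_ids[i], stim_ids[k])))
    }
  }

  true_synchrony <- 25 + 10 * w
  truth <- structure(list(
    stimuli = tibble::tibble(
      stimulus_id = stim_ids, shared_weight = w, valence = valence,
      artist = artist, single = single,
      true_synchrony = true_synchrony,
      expected_log_streams = cfg$beta0 + cfg$beta_synch * true_synchrony +
        cfg$beta_single * as.numeric(single)),
    subjects = tibble::tibble(
      subject_id = subj_ids, alpha_phase = phi, alpha_freq = f_subj,
      faa_offset = faa_offset),
    artifacts = if (length(artifacts)) dplyr::bind_rows(artifacts) else
      tibble::tibble(subject_id = character(), stimulus_id = character(),
                     channel = character(), start_index = integer(),
                     end_index = integer(), amplitude_uv = double())
  ), class = "ground_truth")

  list(recordings = dplyr::bind_rows(rows), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d stimuli, %d subjects, %d injected artifacts\n",
              nrow(x$stimuli), nrow(x$subjects), nrow(x$artifacts)))
  invisible(x)
}
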