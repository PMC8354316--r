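#' Canonical EEG frequency bands
#'
#' Band edges in Hz, inclusive: delta 1-3, theta 4-7, alpha 8-12, beta
#' 13-25, gamma 26-40.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 3), theta = c(4, 7), alpha = c(8, 12),
       beta = c(13, 25), gamma = c(26, 40))
}

#' Spectral analysis configuration
#'
#' @param window_s Sliding-window width in seconds (one tapered segment per
#'   window, Hann taper, no sub-averaging).
#' @param step_s Window step in seconds.
#' @param bands Named list of inclusive band edges in Hz.
#' @return A `spectral_config` list.
#' @export
spectral_config <- function(window_s = 0.5, step_s = 0.25,
                            bands = eeg_bands()) {
  if (window_s <= 0 || step_s <= 0 || step_s > window_s)
    abort("need 0 < step_s <= window_s", class = "neurosync_config_error")
  structure(list(window_s = window_s, step_s = step_s, bands = bands),
            class = "spectral_config")
}

#' Sliding-window band power
#'
#' For each window of `window_s` seconds advanced by `step_s`, computes a
#' Hann-tapered FFT periodogram with density scaling (uV^2/Hz, one-sided)
#' and averages the PSD bins whose centre frequency falls inside each band
#' (inclusive edges). With the default 0.5 s window at 256 Hz the bin grid
#' is 2 Hz, so alpha (8-12 Hz) averages the 8, 10 and 12 Hz bins. Frames
#' overlapping any invalid sample are marked `frame_valid = FALSE` (their
#' power is still computed, but every downstream average excludes them).
#'
#' The frame count is `floor((duration - window_s) / step_s) + 1`; a 24 s
#' fragment at the defaults yields 95 frames. Frame times are window
#' centres.
#'
#' @param rec A preprocessed [eeg_recording()]; `fs >= 128` Hz.
#' @param cfg A [spectral_config()].
#' @return A `band_power` object: power array `channel x band x frame`,
#'   `frame_times` (s), `frame_valid` flags, channel and band labels.
#'   Convert to a tidy tibble with [as_tibble()].
#' @export
#' @examples
#' rec <- eeg_recording(matrix(sin(2 * pi * 10 * (0:511) / 256), 1),
#'                      fs = 256, channels = "Cz")
#' bp <- compute_band_power(rec)
#' dim(bp$power)
compute_band_power <- function(rec, cfg = spectral_config()) {
  if (rec$fs < 128)
    abort("band power needs fs >= 128 Hz", class = "neurosync_config_error")
  L <- round(cfg$window_s * rec$fs)
  step <- round(cfg$step_s * rec$fs)
  n <- ncol(rec$samples)
  if (n < L)
    abort(sprintf("recording (%d samples) shorter than one %d-sample window",
                  n, L))
  n_frames <- (n - L) %/% step + 1L
  starts <- (seq_len(n_frames) - 1L) * step + 1L

  taper <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))  # Hann
  u <- sum(taper^2)
  n_half <- L %/% 2
  freqs <- (0:n_half) * rec$fs / L
  # one-sided density scaling: double everything except DC and Nyquist
  side <- c(1, rep(2, n_half - 1), if (L %% 2 == 0) 1 else 2)
  band_bins <- lapply(cfg$bands, function(e)
    which(freqs >= e[1] & freqs <= e[2]))
  empty <- vapply(band_bins, length, 1L) == 0
  if (any(empty))
    abort(sprintf("no PSD bins fall inside band(s): %s",
                  paste(names(cfg$bands)[empty], collapse = ", ")))

  seg_idx <- outer(0:(L - 1), starts, `+`)        # L x n_frames
  nC <- nrow(rec$samples)
  power <- array(NA_real_, dim = c(nC, length(cfg$bands), n_frames),
                 dimnames = list(rec$channels, names(cfg$bands), NULL))
  for (c in seq_len(nC)) {
    segs <- matrix(rec$samples[c, ][seg_idx], nrow = L) * taper
    spec <- stats::mvfft(segs)[seq_len(n_half + 1L), , drop = FALSE]
    psd <- (Mod(spec)^2) * side / (rec$fs * u)    # uV^2/Hz, one-sided
    for (b in seq_along(band_bins))
      power[c, b, ] <- colMeans(psd[band_bins[[b]], , drop = FALSE])
  }
  frame_valid <- vapply(seq_len(n_frames), function(t)
    all(rec$mask[starts[t]:(starts[t] + L - 1L)]), logical(1))

  structure(list(
    subject_id = rec$subject_id, stimulus_id = rec$stimulus_id,
    fs = rec$fs, channels = rec$channels, bands = names(cfg$bands),
    frame_times = (starts - 1L) / rec$fs + cfg$window_s / 2,
    power = power, frame_valid = frame_valid
  ), class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("<band_power> subject %s, stimulus %s: %d ch x %d bands x %d frames (%d valid)\n",
              x$subject_id, x$stimulus_id, dim(x$power)[1], dim(x$power)[2],
              dim(x$power)[3], sum(x$frame_valid)))
  invisible(x)
}

#' @method as_tibble band_power
#' @export
as_tibble.band_power <- function(x, ...) {
  d <- dim(x$power)
  tibble::tibble(
    subject_id = x$subject_id,
    stimulus_id = x$stimulus_id,
    channel = rep(x$channels, times = d[2] * d[3]),
    band = rep(rep(x$bands, each = d[1]), times = d[3]),
    frame_time = rep(x$frame_times, each = d[1] * d[2]),
    power = as.vector(x$power),
    valid = rep(x$frame_valid, each = d[1] * d[2])
  )
}

#' Band power for every recording of a study
#'
#' @param recordings Tibble with a `recording` list-column.
#' @param cfg A [spectral_config()].
#' @return The tibble with the `recording` column replaced by a `band_power`
#'   list-column.
#' @export
band_power_study <- function(recordings, cfg = spectral_config()) {
  tibble::tibble(
    subject_id = recordings$subject_id,
    stimulus_id = recordings$stimulus_id,
    band_power = lapply(recordings$recording, compute_band_power, cfg = cfg)
  )
}
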