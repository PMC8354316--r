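#' One subject's EEG segment for one stimulus
#'
#' The basic container of the pipeline: a channels-by-samples matrix in
#' microvolts with a per-sample validity mask. The mask starts all-valid and
#' is cleared by [reject_artifacts()]; downstream band-power frames that
#' touch an invalid sample are excluded from every average.
#'
#' @param samples Numeric matrix, channels x samples, microvolts.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of unique channel labels, one per row.
#' @param subject_id,stimulus_id Identifiers.
#' @param mask Logical vector of per-sample validity; defaults to all valid.
#'
#' @return An `eeg_recording` object.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(512), 2, 256), fs = 256,
#'                      channels = c("C3", "C4"),
#'                      subject_id = "s01", stimulus_id = "stim01")
#' rec
eeg_recording <- function(samples, fs, channels,
                          subject_id = NA_character_,
                          stimulus_id = NA_character_,
                          mask = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) abort("`samples` must be a numeric matrix")
  if (length(channels) != nrow(samples))
    abort(sprintf("%d channel labels for %d rows of samples",
                  length(channels), nrow(samples)))
  if (anyDuplicated(channels)) abort("channel labels must be unique")
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be a positive rate in Hz")
  if (is.null(mask)) mask <- rep(TRUE, ncol(samples))
  if (length(mask) != ncol(samples))
    abort("`mask` must have one flag per sample")
  structure(
    list(subject_id = as.character(subject_id),
         stimulus_id = as.character(stimulus_id),
         fs = fs, channels = as.character(channels),
         samples = samples, mask = as.logical(mask)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, stimulus %s: %d ch x %d samples @ %g Hz (%.1f s), %d invalid\n",
              x$subject_id, x$stimulus_id, nrow(x$samples), ncol(x$samples),
              x$fs, ncol(x$samples) / x$fs, sum(!x$mask)))
  invisible(x)
}

#' @method as_tibble eeg_recording
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  n <- ncol(x$samples)
  tibble::tibble(
    subject_id = x$subject_id,
    stimulus_id = x$stimulus_id,
    channel = rep(x$channels, each = n),
    sample_index = rep(seq_len(n) - 1L, times = length(x$channels)),
    microvolts = as.vector(t(x$samples)),
    valid = rep(x$mask, times = length(x$channels))
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# internal: duration helper
rec_duration <- function(rec) ncol(rec$samples) / rec$fs
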