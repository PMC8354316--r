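#' Frontal Alpha Asymmetry for one band-power series
#'
#' Per frame, the natural log of alpha power at F4 minus the natural log of
#' alpha power at F3; averaged over valid frames to one value per
#' (subject, stimulus). Positive values index relatively greater
#' right-frontal alpha power, conventionally read as approach motivation.
#'
#' Frames that are invalid, or where either channel's alpha power is not
#' strictly positive, are excluded (the dropped count is reported).
#'
#' @param bp A `band_power` object containing the `left` and `right`
#'   channels and the configured band.
#' @param band Band name (default `"alpha"`).
#' @param left,right Channel labels (defaults F3 and F4).
#' @return A one-row tibble: `subject_id`, `stimulus_id`, `faa`,
#'   `n_frames_used`, `n_frames_dropped`.
#' @export
compute_faa <- function(bp, band = "alpha", left = "F3", right = "F4") {
  miss <- setdiff(c(left, right), bp$channels)
  if (length(miss))
    abort(sprintf("channels not present for FAA: %s",
                  paste(miss, collapse = ", ")))
  if (!band %in% bp$bands) abort(sprintf("band `%s` not present", band))
  pr <- bp$power[right, band, ]
  pl <- bp$power[left, band, ]
  usable <- bp$frame_valid & pr > 0 & pl > 0
  n_dropped <- sum(bp$frame_valid & !usable)
  if (n_dropped > 0)
    inform(sprintf("FAA %s/%s: %d valid frames dropped for non-positive power",
                   bp$subject_id, bp$stimulus_id, n_dropped))
  tibble::tibble(
    subject_id = bp$subject_id,
    stimulus_id = bp$stimulus_id,
    faa = mean(log(pr[usable]) - log(pl[usable])),
    n_frames_used = sum(usable),
    n_frames_dropped = n_dropped
  )
}

#' Frontal Alpha Asymmetry for every recording of a study
#'
#' @param bp_tbl Tibble from [band_power_study()].
#' @inheritParams compute_faa
#' @return Tibble with one row per (subject, stimulus): `faa` plus frame
#'   bookkeeping.
#' @export
faa_study <- function(bp_tbl, band = "alpha", left = "F3", right = "F4") {
  purrr::map(bp_tbl$band_power, compute_faa,
             band = band, left = left, right = right) %>%
    dplyr::bind_rows()
}

#' Aggregate FAA to the stimulus level
#'
#' Group comparison aggregate: the mean FAA over subjects per stimulus.
#'
#' @param faa_tbl Tibble from [faa_study()].
#' @return Tibble with `stimulus_id` and `faa` (group mean).
#' @export
faa_group <- function(faa_tbl) {
  faa_tbl %>%
    dplyr::group_by(.data$stimulus_id) %>%
    dplyr::summarise(faa = mean(.data$faa), n_subjects = dplyr::n(),
                     .groups = "drop")
}

#' Attach externally supplied engagement scores
#'
#' Engagement probabilities come from an external classifier and are
#' consumed, never computed, by this pipeline. Joins per-(subject,
#' stimulus) scores onto a responses table after validating range and
#' completeness.
#'
#' @param responses Tibble keyed by `subject_id`, `stimulus_id`.
#' @param scores Tibble with `subject_id`, `stimulus_id`, `engagement`
#'   in \[0, 1\].
#' @return `responses` with an `engagement` column.
#' @export
attach_engagement <- function(responses, scores) {
  req <- c("subject_id", "stimulus_id", "engagement")
  if (!all(req %in% names(scores)))
    abort("`scores` needs columns subject_id, stimulus_id, engagement",
          class = "neurosync_validation_error")
  bad <- scores$engagement < 0 | scores$engagement > 1 |
    !is.finite(scores$engagement)
  if (any(bad))
    abort(sprintf("engagement out of [0, 1] for: %s",
                  paste(utils::head(paste0(scores$subject_id[bad], "/",
                                           scores$stimulus_id[bad]), 5),
                        collapse = ", ")),
          class = "neurosync_validation_error")
  responses$engagement <- NULL
  joined <- dplyr::left_join(responses, scores[req],
                             by = c("subject_id", "stimulus_id"))
  missing <- is.na(joined$engagement)
  if (any(missing))
    abort(sprintf("no engagement score for: %s",
                  paste(utils::head(paste0(joined$subject_id[missing], "/",
                                           joined$stimulus_id[missing]), 5),
                        collapse = ", ")),
          class = "neurosync_validation_error")
  joined
}
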