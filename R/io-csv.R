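#' Write EEG recordings to a long-format CSV
#'
#' Columns: `subject_id`, `stimulus_id`, `channel`, `sample_index`
#' (0-based), `microvolts`, `fs`. One row per sample per channel; exact
#' (no quantization), so CSV round trips are bit-stable.
#'
#' @param recordings Tibble with a `recording` list-column, or a list of
#'   [eeg_recording()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(recordings, path) {
  recs <- if (is.data.frame(recordings)) recordings$recording else recordings
  long <- purrr::map(recs, function(r) {
    tb <- as_tibble(r)
    tb$fs <- r$fs
    tb$valid <- NULL
    tb
  }) %>% dplyr::bind_rows()
  # 17 significant digits so doubles survive the text round trip bit-exactly
  long$microvolts <- formatC(long$microvolts, digits = 17, format = "g")
  readr::write_csv(long, path)
  invisible(path)
}

#' Read EEG recordings
#'
#' Reads a study's recordings from either a long-format CSV (explicit
#' `stimulus_id` column; see [write_eeg_csv()]) or a directory of EDF+
#' files (one per subject, stimulus onsets as annotations; see
#' [write_eeg_edf()]). All masks start all-valid.
#'
#' @param path CSV file (`format = "csv"`) or directory of `.edf` files
#'   (`format = "edf"`).
#' @param format `"csv"` or `"edf"`.
#' @return Tibble with `subject_id`, `stimulus_id` and a `recording`
#'   list-column.
#' @export
read_recordings <- function(path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(read_eeg_edf(path))
  long <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            microvolts = readr::col_character()))
  # strtod-based conversion: exact inverse of the 17-digit writer
  long$microvolts <- as.numeric(long$microvolts)
  req <- c("subject_id", "stimulus_id", "channel", "sample_index",
           "microvolts", "fs")
  miss <- setdiff(req, names(long))
  if (length(miss))
    abort(sprintf("CSV is missing columns: %s", paste(miss, collapse = ", ")),
          class = "neurosync_format_error")
  fs <- unique(long$fs)
  if (length(fs) != 1)
    abort(sprintf("mismatched sampling rates across recordings: %s",
                  paste(fs, collapse = ", ")),
          class = "neurosync_format_error")
  channels <- unique(long$channel)
  groups <- split(long, list(long$subject_id, long$stimulus_id), drop = TRUE)
  rows <- purrr::map(unname(groups), function(g) {
    have <- unique(g$channel)
    miss_ch <- setdiff(channels, have)
    if (length(miss_ch))
      abort(sprintf("subject %s, stimulus %s: missing channel(s) %s",
                    g$subject_id[1], g$stimulus_id[1],
                    paste(miss_ch, collapse = ", ")),
            class = "neurosync_format_error")
    g <- g[order(match(g$channel, channels), g$sample_index), ]
    n <- nrow(g) / length(channels)
    X <- matrix(g$microvolts, nrow = length(channels), byrow = TRUE)
    tibble::tibble(subject_id = g$subject_id[1],
                   stimulus_id = g$stimulus_id[1],
                   recording = list(eeg_recording(
                     X, fs, channels, g$subject_id[1], g$stimulus_id[1])))
  })
  dplyr::bind_rows(rows) %>%
    dplyr::arrange(.data$subject_id, .data$stimulus_id)
}

#' Read and validate the study tables
#'
#' Assembles the per-stimulus metadata, outcomes, per-subject ratings and
#' optional engagement and genre tables into one validated `study_tables`
#' object keyed by `stimulus_id`.
#'
#' Validation enforces: unique stimulus ids; ratings integer in 1..5 with
#' no missing (subject, stimulus) cell; non-negative streams. With
#' `units = "raw"` stream counts are divided by one million so all
#' downstream analysis works in millions.
#'
#' @param stimuli CSV with `stimulus_id`, `artist`, `single`.
#' @param outcomes CSV with `stimulus_id`, `streams_early`, `streams_late`.
#' @param ratings CSV with `subject_id`, `stimulus_id`, `rating`.
#' @param engagement Optional CSV with `subject_id`, `stimulus_id`,
#'   `engagement` in \[0, 1\].
#' @param genres Optional CSV with `subject_id`, `genre`, `rank`.
#' @param units `"millions"` (already scaled) or `"raw"` (divide by 1e6).
#' @return A `study_tables` list: `stimuli`, `responses`, `genres`.
#' @export
read_tables <- function(stimuli, outcomes, ratings, engagement = NULL,
                        genres = NULL, units = c("millions", "raw")) {
  units <- match.arg(units)
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE)
  stim <- rd(stimuli); outc <- rd(outcomes); rate <- rd(ratings)

  if (anyDuplicated(stim$stimulus_id))
    abort(sprintf("duplicate stimulus_id in stimuli table: %s",
                  paste(unique(stim$stimulus_id[
                    duplicated(stim$stimulus_id)]), collapse = ", ")),
          class = "neurosync_validation_error")
  if (anyDuplicated(outc$stimulus_id))
    abort("duplicate stimulus_id in outcomes table",
          class = "neurosync_validation_error")
  if (units == "raw") {
    outc$streams_early <- outc$streams_early / 1e6
    outc$streams_late <- outc$streams_late / 1e6
  }
  if (any(outc$streams_early < 0 | outc$streams_late < 0))
    abort("streams must be non-negative",
          class = "neurosync_validation_error")

  bad <- !rate$rating %in% 1:5
  if (any(bad))
    abort(sprintf("ratings outside 1..5 (first offenders: %s)",
                  paste(utils::head(rate$rating[bad], 5), collapse = ", ")),
          class = "neurosync_validation_error")
  grid <- tidyr::expand_grid(subject_id = unique(rate$subject_id),
                             stimulus_id = stim$stimulus_id)
  full <- dplyr::left_join(grid, rate, by = c("subject_id", "stimulus_id"))
  if (any(is.na(full$rating)))
    abort(sprintf("missing rating cells, e.g. %s",
                  paste(utils::head(paste0(
                    full$subject_id[is.na(full$rating)], "/",
                    full$stimulus_id[is.na(full$rating)]), 3),
                    collapse = ", ")),
          class = "neurosync_validation_error")

  responses <- full
  if (!is.null(engagement))
    responses <- attach_engagement(responses, rd(engagement))

  structure(list(
    stimuli = dplyr::inner_join(stim, outc, by = "stimulus_id"),
    responses = responses,
    genres = if (!is.null(genres)) rd(genres) else NULL
  ), class = "study_tables")
}

#' Write the study tables as CSV files
#'
#' Inverse of [read_tables()]: writes `stimuli.csv`, `outcomes.csv`,
#' `ratings.csv`, and when present `engagement.csv` and `genres.csv`.
#'
#' @param tables A `study_tables` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stim_cols <- intersect(c("stimulus_id", "artist", "single"),
                         names(tables$stimuli))
  readr::write_csv(tables$stimuli[stim_cols], file.path(dir, "stimuli.csv"))
  readr::write_csv(
    tables$stimuli[c("stimulus_id", "streams_early", "streams_late")],
    file.path(dir, "outcomes.csv"))
  readr::write_csv(
    tables$responses[c("subject_id", "stimulus_id", "rating")],
    file.path(dir, "ratings.csv"))
  if ("engagement" %in% names(tables$responses))
    readr::write_csv(
      tables$responses[c("subject_id", "stimulus_id", "engagement")],
      file.path(dir, "engagement.csv"))
  if (!is.null(tables$genres))
    readr::write_csv(tables$genres, file.path(dir, "genres.csv"))
  invisible(dir)
}
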