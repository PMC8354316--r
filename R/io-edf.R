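# Minimal EDF+C writer/reader for multi-stimulus EEG studies.
#
# One file per subject: the stimuli are concatenated into a continuous
# recording and each stimulus onset is marked in an "EDF Annotations"
# channel, which is how read_eeg_edf() re-segments the file. Samples are
# quantised to 16 bits over a physical range of +/-1000 uV (resolution
# ~0.031 uV), which leaves headroom beyond the 400 uV artifact gate;
# values outside the range are clipped.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

EDF_PHYS_RANGE <- 1000

#' Write EEG recordings as EDF+ files
#'
#' Writes one EDF+C file per subject. The subject's stimuli are laid out
#' back to back as one continuous signal; each stimulus onset is recorded
#' as an annotation carrying the stimulus id, at a 1 s data-record
#' granularity (recordings are zero-padded to whole seconds).
#'
#' @param recordings Tibble with a `recording` list-column.
#' @param dir Output directory; files are named `<subject_id>.edf`.
#' @return The directory, invisibly.
#' @export
write_eeg_edf <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(recordings$subject_id)) {
    recs <- recordings$recording[recordings$subject_id == sid]
    write_edf_subject(recs, file.path(dir, paste0(sid, ".edf")))
  }
  invisible(dir)
}

write_edf_subject <- function(recs, path) {
  fs <- recs[[1]]$fs
  channels <- recs[[1]]$channels
  if (fs != round(fs)) abort("EDF writer needs an integer sampling rate")
  for (r in recs) {
    if (!identical(r$channels, channels) || r$fs != fs)
      abort("all recordings of a subject must share channels and fs",
            class = "neurosync_format_error")
  }
  # pad each stimulus segment to whole seconds so onsets align to records
  seg_secs <- vapply(recs, function(r) ceiling(ncol(r$samples) / fs), 1)
  onsets <- cumsum(c(0, utils::head(seg_secs, -1)))
  total_secs <- sum(seg_secs)
  X <- matrix(0, length(channels), total_secs * fs)
  for (k in seq_along(recs)) {
    n <- ncol(recs[[k]]$samples)
    X[, onsets[k] * fs + seq_len(n)] <- recs[[k]]$samples
  }
  # EDF digital mapping: dig_min..dig_max spans phys_min..phys_max
  dig <- matrix(as.integer(pmax(-32768, pmin(32767, round(
    (X + EDF_PHYS_RANGE) / (2 * EDF_PHYS_RANGE) * 65535 - 32768)))),
    nrow = nrow(X))

  n_sig <- length(channels) + 1L       # + annotations channel
  ann_samples <- 30L                   # 60 bytes of TALs per record
  n_rec <- total_secs

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate 01-JAN-2001 X X X", 80),
    edf_pad("01.01.01", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + n_sig), 8), edf_pad("EDF+C", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(n_sig, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  labels <- c(channels, "EDF Annotations")
  field(labels, 16)
  field(rep("", n_sig), 80)                                  # transducer
  field(c(rep("uV", n_sig - 1), ""), 8)                      # dimension
  field(c(rep(-EDF_PHYS_RANGE, n_sig - 1), -1), 8)           # phys min
  field(c(rep(EDF_PHYS_RANGE, n_sig - 1), 1), 8)             # phys max
  field(rep(-32768, n_sig), 8)                               # dig min
  field(rep(32767, n_sig), 8)                                # dig max
  field(rep("", n_sig), 80)                                  # prefilter
  field(c(rep(fs, n_sig - 1), ann_samples), 8)               # samples/rec
  field(rep("", n_sig), 32)                                  # reserved

  stim_ids <- vapply(recs, function(r) r$stimulus_id, "")
  for (rec_i in seq_len(n_rec)) {
    t0 <- rec_i - 1L
    idx <- (t0 * fs + 1):(t0 * fs + fs)
    for (c in seq_len(length(channels)))
      writeBin(dig[c, idx], con, size = 2, endian = "little")
    tals <- paste0("+", t0, "\x14\x14")
    hit <- which(onsets == t0)
    for (h in hit)
      tals <- c(tals, paste0("+", t0, "\x14", stim_ids[h], "\x14"))
    # TALs are NUL-terminated; R strings cannot hold nuls, so join as raw
    raw_tal <- unlist(lapply(tals, function(s) c(charToRaw(s), as.raw(0))))
    if (length(raw_tal) > 2 * ann_samples)
      abort("annotation text too long for the EDF record")
    raw_tal <- c(raw_tal, raw(2 * ann_samples - length(raw_tal)))
    writeBin(raw_tal, con)
  }
  invisible(path)
}

#' Read a directory of EDF+ files written by [write_eeg_edf()]
#'
#' Parses each subject's continuous EDF+C file, converts digital values
#' back to microvolts, and segments the signal at the stimulus-onset
#' annotations (half-open segments from each onset to the next onset or
#' the end of file).
#'
#' @param dir Directory of `.edf` files.
#' @return Tibble with `subject_id`, `stimulus_id`, `recording`.
#' @export
read_eeg_edf <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.edf$", full.names = TRUE))
  if (!length(files))
    abort(sprintf("no .edf files in %s", dir), class = "neurosync_format_error")
  all_fs <- numeric()
  rows <- list()
  for (f in files) {
    parsed <- read_edf_subject(f)
    all_fs <- c(all_fs, parsed$fs)
    rows <- c(rows, list(parsed$recordings))
  }
  if (length(unique(all_fs)) != 1)
    abort(sprintf("mismatched sampling rates across EDF files: %s",
                  paste(unique(all_fs), collapse = ", ")),
          class = "neurosync_format_error")
  dplyr::bind_rows(rows) %>%
    dplyr::arrange(.data$subject_id, .data$stimulus_id)
}

read_edf_subject <- function(path) {
  subject_id <- sub("\\.edf$", "", basename(path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_sig <- as.integer(rd(4))
  sig_field <- function(width)
    vapply(seq_len(n_sig), function(i) rd(width), "")
  labels <- sig_field(16)
  sig_field(80); sig_field(8)
  phys_min <- as.numeric(sig_field(8)); phys_max <- as.numeric(sig_field(8))
  dig_min <- as.numeric(sig_field(8)); dig_max <- as.numeric(sig_field(8))
  sig_field(80)
  spr <- as.integer(sig_field(8))
  sig_field(32)

  ann_i <- which(labels == "EDF Annotations")
  eeg_i <- setdiff(seq_len(n_sig), ann_i)
  fs <- spr[eeg_i[1]] / rec_dur
  X <- matrix(0, length(eeg_i), n_rec * spr[eeg_i[1]])
  ann_raw <- list()
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      if (s %in% ann_i) {
        ann_raw[[length(ann_raw) + 1L]] <- readBin(con, "raw", 2 * spr[s])
      } else {
        v <- readBin(con, integer(), spr[s], size = 2, signed = TRUE,
                     endian = "little")
        ci <- match(s, eeg_i)
        scale <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
        X[ci, (r - 1) * spr[s] + seq_len(spr[s])] <-
          phys_min[s] + (v - dig_min[s]) * scale
      }
    }
  }

  ann <- parse_edf_annotations(unlist(ann_raw))
  if (!nrow(ann))
    abort(sprintf("%s: no stimulus onset annotations", path),
          class = "neurosync_format_error")
  ann <- ann[order(ann$onset), ]
  ends <- c(ann$onset[-1], n_rec * rec_dur)
  recs <- purrr::map(seq_len(nrow(ann)), function(k) {
    idx <- (round(ann$onset[k] * fs) + 1):round(ends[k] * fs)
    tibble::tibble(
      subject_id = subject_id, stimulus_id = ann$text[k],
      recording = list(eeg_recording(X[, idx, drop = FALSE], fs,
                                     labels[eeg_i], subject_id,
                                     ann$text[k])))
  })
  list(fs = fs, recordings = dplyr::bind_rows(recs))
}

# Parse the TAL byte stream: "+onset\x14text\x14\x00"; timekeeping TALs
# (empty text) are dropped. NUL separators are handled at the raw level
# because R strings cannot carry embedded nuls.
parse_edf_annotations <- function(bytes) {
  zero <- bytes == as.raw(0)
  grp <- cumsum(zero)
  tals <- vapply(split(bytes[!zero], grp[!zero]), rawToChar, "")
  out <- purrr::map(tals, function(tal) {
    if (!nzchar(tal)) return(NULL)
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(trimws(parts[2]))) return(NULL)
    tibble::tibble(onset = as.numeric(parts[1]), text = trimws(parts[2]))
  })
  out <- purrr::compact(out)
  if (!length(out)) return(tibble::tibble(onset = numeric(), text = character()))
  dplyr::bind_rows(out)
}
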