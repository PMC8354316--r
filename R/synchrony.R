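#' Neural synchrony configuration
#'
#' Parameters of the inter-subject synchrony metric: which electrodes and
#' band are correlated, the half-width of the sliding correlation window in
#' frames, and the reporting scale.
#'
#' With the default 250 ms frame step and `half_width_frames = 2`, each
#' correlation window spans frames t-2..t+2, i.e. -750 to +750 ms of
#' underlying signal around the frame centre.
#'
#' @param electrodes Channel labels entering the correlation (default the
#'   central row C3, Cz, C4).
#' @param band Frequency band name (default alpha).
#' @param half_width_frames Window half-width in frames (>= 1).
#' @param scale Reporting multiplier (100 puts synchrony on a 0-100 scale).
#' @return A `synchrony_config` list.
#' @export
synchrony_config <- function(electrodes = c("C3", "Cz", "C4"),
                             band = "alpha", half_width_frames = 2,
                             scale = 100) {
  if (half_width_frames < 1)
    abort("half_width_frames must be >= 1", class = "neurosync_config_error")
  structure(list(electrodes = electrodes, band = band,
                 half_width_frames = as.integer(half_width_frames),
                 scale = scale),
            class = "synchrony_config")
}

# extract the electrodes x frames power matrix for the configured band
synchrony_matrix <- function(bp, cfg) {
  miss <- setdiff(cfg$electrodes, bp$channels)
  if (length(miss))
    abort(sprintf("electrodes not present in band power: %s",
                  paste(miss, collapse = ", ")))
  if (!cfg$band %in% bp$bands)
    abort(sprintf("band `%s` not present in band power", cfg$band))
  a <- bp$power[cfg$electrodes, cfg$band, , drop = FALSE]
  matrix(a, nrow = length(cfg$electrodes))
}

# flatten the electrodes x (t-hw .. t+hw) submatrix, electrodes fastest
flatten_window <- function(m, t, hw) {
  as.vector(m[, (t - hw):(t + hw), drop = FALSE])
}

#' Windowed pairwise correlation between two subjects
#'
#' The elementary quantity of the synchrony metric: the signed Pearson
#' correlation between two subjects' band-power values in the window of
#' frames t-hw..t+hw over the configured electrodes, each flattened to a
#' single vector (default 5 frames x 3 electrodes = 15 values).
#'
#' @param bp_i,bp_j `band_power` objects on the same frame grid.
#' @param t Frame index (1-based); frames `t - hw` .. `t + hw` must exist
#'   and be valid in both series.
#' @param cfg A [synchrony_config()].
#' @return The signed correlation, or `NA` if either flattened window has
#'   zero variance.
#' @export
window_correlation <- function(bp_i, bp_j, t, cfg = synchrony_config()) {
  hw <- cfg$half_width_frames
  mi <- synchrony_matrix(bp_i, cfg); mj <- synchrony_matrix(bp_j, cfg)
  if (ncol(mi) != ncol(mj) ||
      !isTRUE(all.equal(bp_i$frame_times, bp_j$frame_times)))
    abort("band-power series do not share a frame grid")
  if (t - hw < 1 || t + hw > ncol(mi))
    abort(sprintf("window around frame %d falls outside the frame grid", t))
  win <- (t - hw):(t + hw)
  if (!all(bp_i$frame_valid[win]) || !all(bp_j$frame_valid[win]))
    abort(sprintf("window around frame %d overlaps invalid frames", t))
  suppressWarnings(stats::cor(flatten_window(mi, t, hw),
                              flatten_window(mj, t, hw)))
}

#' Stimulus-level neural synchrony
#'
#' Inter-subject correlation of windowed band power: for every frame t with
#' a full t-hw..t+hw window and every ordered pair of subjects (i, j), the
#' absolute Pearson correlation of the two flattened electrode-by-frame
#' windows is computed; these are averaged over pairs within each frame
#' (denominator N(N-1), i.e. ordered pairs), then over frames, and scaled
#' (default x100, so identical series score 100).
#'
#' Edge frames without a full window are skipped (no padding), so a series
#' of T frames contributes T - 2*hw correlation windows. Windows touching
#' invalid band-power frames are excluded; pair-frames with zero variance
#' are skipped and counted in `n_skipped_pairs`; frames retaining fewer
#' than two valid ordered pairs are dropped entirely.
#'
#' @param bp_list List of `band_power` objects, one per subject, sharing a
#'   frame grid (all for the same stimulus).
#' @param cfg A [synchrony_config()].
#' @return A `synchrony_result`: `synchrony` (scalar, 0-100),
#'   `time_course` tibble (`frame_time`, `synchrony`, `n_pairs`),
#'   `pair_matrix` (N x N mean absolute pairwise correlation, diagonal
#'   `NA`), `n_valid_frames`, `n_skipped_pairs`.
#' @export
neural_synchrony <- function(bp_list, cfg = synchrony_config()) {
  n_sub <- length(bp_list)
  if (n_sub < 2)
    abort("neural synchrony needs at least 2 subjects",
          class = "neurosync_input_error")
  mats <- lapply(bp_list, synchrony_matrix, cfg = cfg)
  n_frames <- unique(vapply(mats, ncol, 1L))
  if (length(n_frames) != 1)
    abort("band-power series do not share a frame grid")
  hw <- cfg$half_width_frames
  nw <- n_frames - 2L * hw
  if (nw < 1) abort("too few frames for the correlation window")
  ne <- length(cfg$electrodes)
  wlen <- ne * (2L * hw + 1L)

  # per subject: flattened windows (wlen x nw) and window validity
  offs <- as.vector(outer(seq_len(ne), (0:(2 * hw)) * ne, `+`))
  wins <- vector("list", n_sub); wvalid <- matrix(TRUE, n_sub, nw)
  for (i in seq_len(n_sub)) {
    m <- mats[[i]]
    idx <- outer(offs, (seq_len(nw) - 1L) * ne, `+`)
    wins[[i]] <- matrix(as.vector(m)[idx], nrow = wlen)
    fv <- bp_list[[i]]$frame_valid
    wvalid[i, ] <- vapply(seq_len(nw), function(t)
      all(fv[t:(t + 2L * hw)]), logical(1))
  }

  # absolute correlation per unordered pair and window
  pairs <- utils::combn(n_sub, 2)
  np <- ncol(pairs)
  P <- matrix(NA_real_, np, nw)
  skipped <- 0L
  for (p in seq_len(np)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ok <- which(wvalid[i, ] & wvalid[j, ])
    for (tt in ok) {
      r <- suppressWarnings(stats::cor(wins[[i]][, tt], wins[[j]][, tt]))
      if (is.na(r)) skipped <- skipped + 1L else P[p, tt] <- abs(r)
    }
  }

  # ordered-pair reduction: every unordered value enters twice, in the
  # (i, j != i) order of the double sum
  pid <- matrix(0L, n_sub, n_sub)
  for (p in seq_len(np)) {
    pid[pairs[1, p], pairs[2, p]] <- p
    pid[pairs[2, p], pairs[1, p]] <- p
  }
  ord <- pid[cbind(rep(seq_len(n_sub), each = n_sub),
                   rep(seq_len(n_sub), times = n_sub))]
  ord <- ord[ord > 0L]                       # drops the i == j diagonal
  Pord <- P[ord, , drop = FALSE]
  n_pairs_valid <- colSums(!is.na(Pord))
  tc <- colSums(Pord, na.rm = TRUE) / n_pairs_valid
  keep <- n_pairs_valid >= 2
  if (!any(keep)) {
    abort(paste0("no valid frames for synchrony: ",
                 sprintf("%d/%d windows invalid per subject on average",
                         round(mean(1 - wvalid) * nw), nw)),
          class = "neurosync_input_error")
  }

  centre_times <- bp_list[[1]]$frame_times[(hw + 1):(n_frames - hw)]
  structure(list(
    stimulus_id = bp_list[[1]]$stimulus_id,
    synchrony = cfg$scale * mean(tc[keep]),
    time_course = tibble::tibble(
      frame_time = centre_times[keep],
      synchrony = cfg$scale * tc[keep],
      n_pairs = n_pairs_valid[keep]),
    pair_matrix = {
      pm <- matrix(NA_real_, n_sub, n_sub)
      rm_ <- rowMeans(P, na.rm = TRUE)
      for (p in seq_len(np)) {
        pm[pairs[1, p], pairs[2, p]] <- rm_[p]
        pm[pairs[2, p], pairs[1, p]] <- rm_[p]
      }
      pm
    },
    n_valid_frames = sum(keep),
    n_skipped_pairs = skipped,
    scale = cfg$scale
  ), class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("<synchrony_result> stimulus %s: synchrony %.2f (0-%g scale), %d valid frames, %d skipped pair-frames\n",
              x$stimulus_id, x$synchrony, x$scale, x$n_valid_frames,
              x$n_skipped_pairs))
  invisible(x)
}

#' Neural synchrony for every stimulus of a study
#'
#' Groups the study's band-power series by stimulus and runs
#' [neural_synchrony()] on each group.
#'
#' @param bp_tbl Tibble from [band_power_study()].
#' @param cfg A [synchrony_config()].
#' @return Tibble with `stimulus_id`, `synchrony`, `n_valid_frames`,
#'   `n_skipped_pairs` and a `result` list-column of full
#'   `synchrony_result` objects.
#' @export
synchrony_study <- function(bp_tbl, cfg = synchrony_config()) {
  split(bp_tbl, bp_tbl$stimulus_id) %>%
    purrr::map(function(g) {
      res <- neural_synchrony(g$band_power, cfg)
      tibble::tibble(stimulus_id = res$stimulus_id,
                     synchrony = res$synchrony,
                     n_valid_frames = res$n_valid_frames,
                     n_skipped_pairs = res$n_skipped_pairs,
                     result = list(res))
    }) %>%
    dplyr::bind_rows() %>%
    dplyr::arrange(.data$stimulus_id)
}
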