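#' Simulate streaming outcomes, ratings, engagement and genre preferences
#'
#' The generative twin of the popularity analysis. Streaming counts follow a
#' log-linear model in the noise-free synchrony proxy and the
#' single-release flag:
#' `log(streams_early) = beta0 + beta_synch * true_synchrony +
#' beta_single * single + Normal(0, noise_sd)` (streams in millions). The
#' late horizon is the early horizon scaled by `growth_factor` with
#' additional log-normal noise (SD 0.1). Per-subject 1-5 ratings come from a
#' cumulative-logit ordinal model whose latent scale is centred on the
#' stimulus valence (fixed cutpoints -1.5, -0.5, 0.5, 1.5). Engagement is a
#' logistic transform of a latent score with a configurable (negative by
#' default) loading of valence, plus observation noise, clipped to \[0, 1\].
#' Genre preferences rank six genres per subject with roughly 53% of
#' subjects ranking pop first.
#'
#' Uses `config$seed + 1L` so it is reproducible independently of
#' [simulate_eeg()].
#'
#' @param truth A `ground_truth` from [simulate_eeg()].
#' @param config The same [study_config()].
#' @return A `study_tables` list with
#'   * `stimuli`: per-stimulus tibble (`stimulus_id`, `artist`, `single`,
#'     `streams_early`, `streams_late`, true parameters);
#'   * `responses`: long tibble (`subject_id`, `stimulus_id`, `rating`,
#'     `engagement`);
#'   * `genres`: long tibble (`subject_id`, `genre`, `rank`).
#' @export
#' @examples
#' cfg <- study_config(n_subjects = 4, n_stimuli = 3, duration_s = 2)
#' sim <- simulate_eeg(cfg)
#' tab <- simulate_outcomes(sim$truth, cfg)
#' tab$stimuli
simulate_outcomes <- function(truth, config) {
  cfg <- validate_study_config(config)
  if (!inherits(truth, "ground_truth")) abort("`truth` must be a ground_truth")
  set.seed(cfg$seed + 1L)
  st <- truth$stimuli
  nK <- nrow(st); nS <- nrow(truth$subjects)

  log_early <- st$expected_log_streams + stats::rnorm(nK, 0, cfg$noise_sd)
  log_late <- log_early + log(cfg$growth_factor) + stats::rnorm(nK, 0, 0.1)

  stimuli <- tibble::tibble(
    stimulus_id = st$stimulus_id,
    artist = st$artist,
    single = st$single,
    streams_early = exp(log_early),
    streams_late = exp(log_late),
    shared_weight = st$shared_weight,
    valence = st$valence,
    true_synchrony = st$true_synchrony
  )

  # ratings: cumulative-logit with fixed cutpoints, latent centred on valence
  cutpoints <- c(-1.5, -0.5, 0.5, 1.5)
  grid <- tidyr::expand_grid(subject_id = truth$subjects$subject_id,
                             stimulus_id = st$stimulus_id)
  latent <- rep(st$valence, times = nS) + stats::rlogis(nS * nK)
  rating <- findInterval(latent, cutpoints) + 1L

  eng_latent <- -2 + cfg$engagement_loading * rep(st$valence, times = nS) +
    stats::rnorm(nS * nK, 0, 0.5)
  engagement <- pmin(1, pmax(0, stats::plogis(eng_latent) +
                                  stats::rnorm(nS * nK, 0, 0.02)))
  responses <- dplyr::mutate(grid, rating = rating, engagement = engagement)

  # genre preferences: ~53% pop-first, favourite gets rank 1
  genres <- c("rock", "pop", "alternative", "hiphop_rap", "jazz_blues", "rnb")
  n_pop <- round(nS * 16 / 30)
  pop_first <- sample(rep(c(TRUE, FALSE), times = c(n_pop, nS - n_pop)))
  genre_rows <- purrr::map2(truth$subjects$subject_id, pop_first,
    function(sid, is_pop) {
      fav <- if (is_pop) "pop" else sample(setdiff(genres, "pop"), 1)
      rest <- sample(setdiff(genres, fav))
      tibble::tibble(subject_id = sid, genre = c(fav, rest),
                     rank = seq_along(genres))
    })

  structure(list(stimuli = stimuli, responses = responses,
                 genres = dplyr::bind_rows(genre_rows)),
            class = "study_tables")
}

#' @export
print.study_tables <- function(x, ...) {
  cat(sprintf("<study_tables> %d stimuli, %d responses (%d subjects)\n",
              nrow(x$stimuli), nrow(x$responses),
              dplyr::n_distinct(x$responses$subject_id)))
  invisible(x)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_eeg()] then [simulate_outcomes()].
#'
#' @param config A [study_config()].
#' @return A list with `recordings`, `truth` and `tables`.
#' @export
simulate_study <- function(config = study_config()) {
  sim <- simulate_eeg(config)
  tables <- simulate_outcomes(sim$truth, config)
  list(recordings = sim$recordings, truth = sim$truth, tables = tables)
}
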