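#' Kendall correlations of neural metrics with likeability
#'
#' Individual-level analysis: because ratings are ordinal (1-5 Likert),
#' Kendall's tau-b is used throughout. Each metric is correlated with the
#' rating over all (subject, stimulus) observations, with Bonferroni
#' control over the metric family (default two tests at family alpha 0.05,
#' i.e. a per-test threshold of 0.025).
#'
#' @param responses Long tibble with `rating` and one column per metric.
#' @param metrics Metric column names (default `faa` and `engagement`).
#' @param alpha_family Family-wise error rate.
#' @param m_tests Number of tests in the family (defaults to the number of
#'   metrics).
#' @return Tibble with one `correlation_report` row per metric.
#' @export
likeability_correlations <- function(responses,
                                     metrics = c("faa", "engagement"),
                                     alpha_family = 0.05,
                                     m_tests = length(metrics)) {
  miss <- setdiff(c("rating", metrics), names(responses))
  if (length(miss))
    abort(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  thr <- alpha_family / m_tests
  purrr::map(metrics, function(mname) {
    ok <- stats::complete.cases(responses$rating, responses[[mname]])
    x <- responses[[mname]][ok]; y <- responses$rating[ok]
    if (stats::sd(x) == 0)
      abort(sprintf("metric `%s` is constant", mname),
            class = "neurosync_input_error")
    ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                           exact = FALSE))
    tibble::tibble(pair = paste0(mname, "~rating"), method = "kendall",
                   statistic = unname(ct$estimate), p.value = ct$p.value,
                   n = sum(ok), bonferroni_alpha = thr,
                   significant = ct$p.value < thr)
  }) %>% dplyr::bind_rows()
}

#' Binarize genre preference into a pop-fan flag
#'
#' Collapses each subject's ranked genre list (ranks must be a permutation
#' of 1..number of genres; rank 1 = best liked) to a single boolean:
#' whether pop is the favourite.
#'
#' @param genres Long tibble with `subject_id`, `genre`, `rank`.
#' @param target Genre defining the flag (default `"pop"`).
#' @param levels Allowed genre labels.
#' @return Tibble with `subject_id` and `pop_fan`.
#' @export
binarize_genre <- function(genres,
                           target = "pop",
                           levels = c("rock", "pop", "alternative",
                                      "hiphop_rap", "jazz_blues", "rnb")) {
  unknown <- setdiff(unique(genres$genre), levels)
  if (length(unknown))
    abort(sprintf("unknown genre label(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "neurosync_validation_error")
  split(genres, genres$subject_id) %>%
    purrr::map(function(g) {
      r <- sort(g$rank)
      if (!identical(as.integer(r), seq_along(r)))
        abort(sprintf(
          "subject %s: ranks must be a permutation of 1..%d (got %s)",
          g$subject_id[1], nrow(g), paste(g$rank, collapse = ",")),
          class = "neurosync_validation_error")
      tibble::tibble(subject_id = g$subject_id[1],
                     pop_fan = g$genre[g$rank == 1] == target)
    }) %>%
    dplyr::bind_rows()
}

# AIC of a fitted candidate model
fit_candidate <- function(data, outcome, terms, family) {
  fml <- stats::as.formula(paste(
    outcome, "~", if (length(terms)) paste(terms, collapse = " + ") else "1"))
  if (family == "linear") stats::lm(fml, data = data)
  else stats::glm(fml, data = data, family = stats::binomial())
}

#' Stepwise model selection by AIC
#'
#' Bidirectional stepwise search for the model of individual likeability:
#' starting from the intercept-only model, at every step the single
#' addition or removal of a candidate term that most decreases AIC is
#' applied; the search stops when no move decreases AIC. The full trace is
#' retained, and the final model's AIC is never above any visited model's.
#'
#' Two outcome families are provided, reflecting the ambiguity of running
#' a 5-level Likert outcome through a "logistic" selection: `"linear"`
#' (default) fits OLS on the raw 1-5 score; `"logistic"` fits a binomial
#' GLM on the rating dichotomised at >= `logistic_cut`. If the logistic
#' family separates perfectly, the search falls back to the linear family
#' with a warning and a flag.
#'
#' @param data Long tibble of complete observations.
#' @param outcome Outcome column (default `"rating"`).
#' @param candidates Candidate term columns (default engagement, faa,
#'   artist, single, pop_fan).
#' @param family `"linear"` or `"logistic"`.
#' @param logistic_cut Threshold for dichotomising the rating in the
#'   logistic family.
#' @return A `stepwise_fit`: final `fit`, `terms`, `aic`, `family`,
#'   `fallback` flag and a `trace` tibble (`step`, `action`, `term`,
#'   `aic`).
#' @export
stepwise_aic <- function(data, outcome = "rating",
                         candidates = c("engagement", "faa", "artist",
                                        "single", "pop_fan"),
                         family = c("linear", "logistic"),
                         logistic_cut = 4) {
  family <- match.arg(family)
  if (length(candidates) < 2) abort("need at least 2 candidate terms")
  miss <- setdiff(c(outcome, candidates), names(data))
  if (length(miss))
    abort(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  data <- data[stats::complete.cases(data[c(outcome, candidates)]), ]

  fallback <- FALSE
  if (family == "logistic") {
    data[[outcome]] <- as.integer(data[[outcome]] >= logistic_cut)
    sep <- withCallingHandlers({
      fit_all <- fit_candidate(data, outcome, candidates, "logistic")
      any(stats::fitted(fit_all) > 1 - 1e-8 | stats::fitted(fit_all) < 1e-8)
    }, warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
    if (isTRUE(sep)) {
      warn("separation in the logistic family; falling back to linear")
      family <- "linear"; fallback <- TRUE
    }
  }

  current <- character()
  fit <- fit_candidate(data, outcome, current, family)
  aic <- stats::AIC(fit)
  trace <- list(tibble::tibble(step = 0L, action = "start",
                               term = "(intercept)", aic = aic))
  step <- 0L
  repeat {
    moves <- dplyr::bind_rows(
      if (length(setdiff(candidates, current)))
        tibble::tibble(action = "add", term = setdiff(candidates, current)),
      if (length(current))
        tibble::tibble(action = "drop", term = current)
    )
    if (!nrow(moves)) break
    move_aic <- vapply(seq_len(nrow(moves)), function(m) {
      trial <- if (moves$action[m] == "add") c(current, moves$term[m])
        else setdiff(current, moves$term[m])
      stats::AIC(fit_candidate(data, outcome, trial, family))
    }, numeric(1))
    best <- which.min(move_aic)
    if (move_aic[best] >= aic) break
    current <- if (moves$action[best] == "add") c(current, moves$term[best])
      else setdiff(current, moves$term[best])
    aic <- move_aic[best]
    fit <- fit_candidate(data, outcome, current, family)
    step <- step + 1L
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = step, action = moves$action[best], term = moves$term[best],
      aic = aic)
  }

  structure(list(fit = fit, terms = current, aic = aic, family = family,
                 fallback = fallback, trace = dplyr::bind_rows(trace),
                 n = nrow(data)),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> %s family, %d obs: %s (AIC = %.2f%s)\n",
              x$family, x$n,
              if (length(x$terms)) paste(x$terms, collapse = " + ")
              else "(intercept only)",
              x$aic, if (x$fallback) ", logistic fallback" else ""))
  invisible(x)
}
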