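#' Remove univariate outliers by the 3-SD rule
#'
#' Single pass: mean and SD are computed once on the full input, and every
#' value whose absolute deviation from that mean strictly exceeds `k` SDs
#' is removed. The rule is deliberately not iterated, so a second extreme
#' value unmasked by the first removal stays in. If the SD is zero nothing
#' is removed.
#'
#' @param values Numeric vector (n >= 3).
#' @param k SD multiplier (default 3).
#' @return A list: `kept` (values), `kept_idx`, `removed_idx`, `removed`
#'   (values), `mean`, `sd` (full-sample statistics the rule used).
#' @export
#' @examples
#' remove_univariate_outliers(c(rnorm(23, 4, 1), 20))$removed
remove_univariate_outliers <- function(values, k = 3) {
  if (length(values) < 3) abort("need at least 3 values")
  m <- mean(values); s <- stats::sd(values)
  removed_idx <- if (s > 0) which(abs(values - m) > k * s) else integer()
  list(kept = values[setdiff(seq_along(values), removed_idx)],
       kept_idx = setdiff(seq_along(values), removed_idx),
       removed_idx = removed_idx, removed = values[removed_idx],
       mean = m, sd = s)
}

#' Screen for multivariate outliers by Mahalanobis distance
#'
#' Computes each row's squared Mahalanobis distance from the multivariate
#' mean and flags rows beyond the chi-square quantile (default 0.975, p
#' degrees of freedom). This is a screen only - flagged rows are reported
#' for review, not removed; removal remains the univariate 3-SD rule.
#'
#' @param x Numeric matrix or data frame of variables (n > p).
#' @param quantile Chi-square quantile used as the flagging threshold.
#' @return Tibble with `row`, `distance2`, `flagged`.
#' @export
mahalanobis_screen <- function(x, quantile = 0.975) {
  x <- as.matrix(x)
  if (nrow(x) <= ncol(x))
    abort("need more rows than variables for a Mahalanobis screen")
  cv <- stats::cov(x)
  if (inherits(try(solve(cv), silent = TRUE), "try-error"))
    abort("singular covariance; reduce the variable set before screening")
  d2 <- stats::mahalanobis(x, colMeans(x), cv)
  thr <- stats::qchisq(quantile, df = ncol(x))
  tibble::tibble(row = seq_len(nrow(x)), distance2 = d2,
                 flagged = d2 > thr)
}

#' Normality-gated correlation with Bonferroni control
#'
#' Each variable is tested for normality (Shapiro-Wilk at
#' `normality_alpha`). If both pass, a Pearson correlation is used;
#' otherwise Kendall's tau-b (tie-corrected, suited to ordinal and
#' non-normal data). Significance is judged against the Bonferroni
#' per-test threshold `alpha_family / m_tests`.
#'
#' @param x,y Paired numeric vectors (n >= 4).
#' @param alpha_family Family-wise error rate.
#' @param m_tests Number of tests in the family.
#' @param normality_alpha Alpha for the Shapiro-Wilk gates.
#' @param pair Optional label for the report.
#' @return A one-row tibble (`correlation_report`): `pair`, `method`,
#'   `statistic`, `p.value`, `n`, `bonferroni_alpha`, `significant`,
#'   `shapiro_p_x`, `shapiro_p_y`.
#' @export
gated_correlation <- function(x, y, alpha_family = 0.05, m_tests = 8,
                              normality_alpha = 0.05, pair = "x~y") {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) abort("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("constant variable; correlation undefined",
          class = "neurosync_input_error")
  sw_x <- stats::shapiro.test(x)$p.value
  sw_y <- stats::shapiro.test(y)$p.value
  method <- if (sw_x >= normality_alpha && sw_y >= normality_alpha)
    "pearson" else "kendall"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  thr <- alpha_family / m_tests
  tibble::tibble(
    pair = pair, method = method,
    statistic = unname(ct$estimate), p.value = ct$p.value, n = length(x),
    bonferroni_alpha = thr, significant = ct$p.value < thr,
    shapiro_p_x = sw_x, shapiro_p_y = sw_y
  )
}

#' Fit a popularity regression with assumption checks
#'
#' Ordinary least squares of a streaming outcome on stimulus-level terms,
#' with the diagnostic-gated log transform: residual normality
#' (Shapiro-Wilk) and homoscedasticity (Breusch-Pagan) are checked on the
#' untransformed fit, and if either fails at `diagnostic_alpha` the model
#' is refit on the natural log of the outcome. On the log scale a
#' coefficient b is interpreted through the log-normal mean as the
#' multiplicative factor exp(b + sigma^2/2) per unit predictor; on the raw
#' scale the interpreted effect is b itself.
#'
#' @param data Per-stimulus tibble with the outcome column and the columns
#'   named by `terms` (`synchrony`, `single`, `ratings` i.e. group-mean
#'   rating, `early_streams`).
#' @param outcome `"early"` or `"late"` (columns `streams_early` /
#'   `streams_late`), or any column name.
#' @param terms Character vector of predictors.
#' @param diagnostic_alpha Alpha for the two diagnostics.
#' @param force_transform `NA` (gate on diagnostics, the default), or
#'   `TRUE`/`FALSE` to force the transform decision.
#' @return A `popularity_fit`: the `lm` fit, `transform` flag,
#'   diagnostics on the reported fit, interpreted multipliers, and the
#'   diagnostics of the untransformed fit that triggered the gate.
#'   `tidy()`, `glance()` and `autoplot()` methods are provided.
#' @export
fit_popularity_model <- function(data, outcome = c("early", "late"),
                                 terms = c("synchrony", "single"),
                                 diagnostic_alpha = 0.05,
                                 force_transform = NA) {
  col_map <- c(early = "streams_early", late = "streams_late")
  outcome_col <- if (outcome[1] %in% names(col_map)) col_map[[outcome[1]]]
    else outcome[1]
  term_map <- c(synchrony = "synchrony", single = "single",
                ratings = "rating", early_streams = "streams_early")
  term_cols <- ifelse(terms %in% names(term_map), term_map[terms], terms)
  need <- c(outcome_col, term_cols)
  miss <- setdiff(need, names(data))
  if (length(miss))
    abort(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  df <- data[stats::complete.cases(data[need]), need]
  if (nrow(df) < length(terms) + 2)
    abort("too few rows for the requested model")
  if (any(df[[outcome_col]] <= 0))
    abort("outcome must be strictly positive (streams in millions)")

  fml <- stats::as.formula(paste(outcome_col, "~",
                                 paste(term_cols, collapse = " + ")))
  fit_raw <- stats::lm(fml, data = df)
  check_collinearity(fit_raw, term_cols)
  diag_raw <- regression_diagnostics(fit_raw)

  transform <- if (is.na(force_transform)) {
    diag_raw$shapiro_p < diagnostic_alpha || diag_raw$bp_p < diagnostic_alpha
  } else isTRUE(force_transform)

  if (transform) {
    df$.log_outcome <- log(df[[outcome_col]])
    fml_t <- stats::as.formula(paste(".log_outcome ~",
                                     paste(term_cols, collapse = " + ")))
    fit <- stats::lm(fml_t, data = df)
  } else fit <- fit_raw

  s2 <- summary(fit)$sigma^2
  b <- stats::coef(fit)
  multipliers <- if (transform) exp(b + s2 / 2) else b

  structure(list(
    outcome = outcome_col,
    transform = if (transform) "log" else "none",
    fit = fit, data = df, terms = term_cols,
    diagnostics = regression_diagnostics(fit),
    diagnostics_untransformed = diag_raw,
    sigma2 = s2, multipliers = multipliers, n = nrow(df)
  ), class = "popularity_fit")
}

check_collinearity <- function(fit, term_cols) {
  alias <- stats::alias(fit)$Complete
  if (!is.null(alias) && nrow(alias) > 0)
    abort(sprintf("perfect collinearity among terms: %s",
                  paste(rownames(alias), collapse = ", ")),
          class = "neurosync_input_error")
}

regression_diagnostics <- function(fit) {
  res <- stats::residuals(fit)
  # a perfect fit carries no evidence against either assumption
  if (stats::sd(res) < 1e-10)
    return(list(shapiro_w = 1, shapiro_p = 1, bp_stat = 0, bp_p = 1))
  sw <- stats::shapiro.test(res)
  bp <- lmtest::bptest(fit)
  list(shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
       bp_stat = unname(bp$statistic), bp_p = bp$p.value)
}

#' @export
print.popularity_fit <- function(x, ...) {
  cat(sprintf("<popularity_fit> %s%s ~ %s  (n = %d)\n",
              if (x$transform == "log") "log " else "", x$outcome,
              paste(x$terms, collapse = " + "), x$n))
  s <- summary(x$fit)
  cat(sprintf("  adj R2 = %.3f | Shapiro p = %.3f | Breusch-Pagan p = %.3f\n",
              s$adj.r.squared, x$diagnostics$shapiro_p, x$diagnostics$bp_p))
  mult_label <- if (x$transform == "log") "exp(b + s2/2)" else "b"
  m <- x$multipliers
  cat(sprintf("  interpreted effects (%s): %s\n", mult_label,
              paste(sprintf("%s = %.3f", names(m), m), collapse = ", ")))
  invisible(x)
}

#' Compare nested popularity models by a partial F test
#'
#' Tests whether the extended model's extra terms significantly reduce the
#' residual sum of squares. Both fits must model the same outcome on the
#' same rows under the same transform, and the base terms must be a strict
#' subset of the extended terms.
#'
#' @param base,extended `popularity_fit` objects.
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
compare_nested <- function(base, extended) {
  if (!inherits(base, "popularity_fit") ||
      !inherits(extended, "popularity_fit"))
    abort("both arguments must be popularity_fit objects")
  if (base$outcome != extended$outcome || base$transform != extended$transform)
    abort("models are not comparable: different outcome or transform",
          class = "neurosync_input_error")
  if (base$n != extended$n)
    abort("models were fit on different rows", class = "neurosync_input_error")
  if (!all(base$terms %in% extended$terms) ||
      length(base$terms) >= length(extended$terms))
    abort("`base` terms must be a strict subset of `extended` terms",
          class = "neurosync_input_error")
  an <- stats::anova(base$fit, extended$fit)
  f <- an$F[2]
  if (is.na(f) && an$`Sum of Sq`[2] < 1e-12) f <- 0  # duplicate-predictor edge
  tibble::tibble(statistic = f, df1 = an$Df[2], df2 = an$Res.Df[2],
                 p.value = if (f == 0) 1 else an$`Pr(>F)`[2])
}
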