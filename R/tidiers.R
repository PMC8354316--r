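# broom-style verbs for the fitted objects

#' @rdname fit_popularity_model
#' @param x A `popularity_fit`.
#' @param ... Unused.
#' @method tidy popularity_fit
#' @export
tidy.popularity_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4],
    multiplier = unname(x$multipliers[rownames(s)])
  )
}

#' @rdname fit_popularity_model
#' @method glance popularity_fit
#' @export
glance.popularity_fit <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma2 = x$sigma2,
    statistic = unname(f[1]),
    p.value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    shapiro_w = x$diagnostics$shapiro_w,
    shapiro_p = x$diagnostics$shapiro_p,
    bp_stat = x$diagnostics$bp_stat, bp_p = x$diagnostics$bp_p,
    transform = x$transform, n = x$n
  )
}

#' @rdname stepwise_aic
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @method tidy stepwise_fit
#' @export
tidy.stepwise_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @rdname stepwise_aic
#' @method glance stepwise_fit
#' @export
glance.stepwise_fit <- function(x, ...) {
  tibble::tibble(aic = x$aic, family = x$family, fallback = x$fallback,
                 n = x$n, n_steps = max(x$trace$step))
}

#' @rdname neural_synchrony
#' @param x A `synchrony_result`.
#' @param ... Unused.
#' @method tidy synchrony_result
#' @export
tidy.synchrony_result <- function(x, ...) x$time_course

#' @rdname neural_synchrony
#' @method glance synchrony_result
#' @export
glance.synchrony_result <- function(x, ...) {
  tibble::tibble(stimulus_id = x$stimulus_id, synchrony = x$synchrony,
                 n_valid_frames = x$n_valid_frames,
                 n_skipped_pairs = x$n_skipped_pairs)
}
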