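#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter-plus-fit plot for a popularity model
#'
#' Streams (log scale when the model was log transformed) against the
#' chosen predictor, with the fitted regression line in blue, its
#' confidence band in grey, and single releases drawn as triangles when a
#' `single` column is present.
#'
#' @param object A `popularity_fit`.
#' @param predictor Which term to place on the x axis (default the first
#'   numeric term).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot popularity_fit
#' @export
autoplot.popularity_fit <- function(object, predictor = NULL, ...) {
  df <- object$data
  num_terms <- object$terms[vapply(object$terms, function(t)
    is.numeric(df[[t]]), logical(1))]
  predictor <- predictor %||% num_terms[1]
  if (is.na(predictor)) abort("no numeric term to plot against")
  yvar <- if (object$transform == "log") ".log_outcome" else object$outcome
  ylab <- if (object$transform == "log")
    paste0("log ", object$outcome, " (millions)")
  else paste0(object$outcome, " (millions)")

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[predictor]],
                                        y = .data[[yvar]]))
  if ("single" %in% names(df)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(shape = .data$single, colour = .data$single), size = 2) +
      ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                              `TRUE` = "blue"))
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::geom_smooth(formula = y ~ x, method = "lm", colour = "blue",
                         fill = "grey70", alpha = 0.4) +
    ggplot2::labs(x = predictor, y = ylab) +
    ggplot2::theme_minimal()
}

#' Time-course plot for a synchrony result
#'
#' Per-frame mean absolute pairwise correlation over time, with an
#' optional centred rolling-mean smoother for qualitative reading (the
#' scalar metric itself is never smoothed).
#'
#' @param object A `synchrony_result`.
#' @param smooth_frames Width of the optional rolling mean in frames
#'   (0 = none).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot synchrony_result
#' @export
autoplot.synchrony_result <- function(object, smooth_frames = 0, ...) {
  tc <- object$time_course
  p <- ggplot2::ggplot(tc, ggplot2::aes(x = .data$frame_time,
                                        y = .data$synchrony)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_hline(yintercept = object$synchrony, linetype = 2,
                        colour = "blue") +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("synchrony (0-%g)", object$scale),
                  title = sprintf("stimulus %s: synchrony %.1f",
                                  object$stimulus_id, object$synchrony)) +
    ggplot2::theme_minimal()
  if (smooth_frames > 1) {
    sm <- stats::filter(tc$synchrony, rep(1 / smooth_frames, smooth_frames))
    p <- p + ggplot2::geom_line(data = tc[!is.na(sm), ],
                                ggplot2::aes(y = sm[!is.na(sm)]),
                                colour = "blue", linewidth = 0.8)
  }
  p
}
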