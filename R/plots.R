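#' Plot a recurrence plot
#'
#' @param object A [recurrence_plot()].
#' @param ... Unused.
#' @return A ggplot raster of the binary recurrence matrix (time runs
#'   upward on the y axis, as is conventional).
#' @method autoplot recurrence_plot
#' @export
autoplot.recurrence_plot <- function(object, ...) {
  d <- tidyr::expand_grid(i = seq_len(object$n), j = seq_len(object$n))
  d$recurrent <- as.vector(object$matrix)
  ggplot2::ggplot(d[d$recurrent, ], ggplot2::aes(x = .data$j, y = .data$i)) +
    ggplot2::geom_raster(fill = "#2c5aa0") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "time j", y = "time i",
                  title = sprintf("Recurrence plot (radius = %g, %%REC = %.2f)",
                                  object$params$radius,
                                  recurrence_rate(object))) +
    ggplot2::theme_minimal()
}

#' Plot a diagonal recurrence profile
#'
#' @param object A [diagonal_profile()] tibble.
#' @param log Draw on log-log axes? Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot line plot of recurrence rate against lag.
#' @method autoplot diag_profile
#' @export
autoplot.diag_profile <- function(object, log = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$rec_rate)) +
    ggplot2::geom_line(color = "#2c5aa0") +
    ggplot2::labs(x = "lag (diagonal index)", y = "recurrence rate") +
    ggplot2::theme_minimal()
  if (log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Plot a scaling fit
#'
#' @param object A `scaling_fit`.
#' @param ... Unused.
#' @return A ggplot of the fitted points and OLS line in fit coordinates.
#' @method autoplot scaling_fit
#' @export
autoplot.scaling_fit <- function(object, ...) {
  lab <- if (object$space == "log-log") c("log x", "log y") else c("x", "y")
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         color = "#c0392b") +
    ggplot2::labs(x = lab[1], y = lab[2],
                  title = sprintf("%s: slope = %.3f, R² = %.3f",
                                  object$estimator, object$slope,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot DFA fluctuations
#'
#' @param object A [dfa_fluctuation()] tibble.
#' @param ... Unused.
#' @return A ggplot of `F(n)` against window size on log-log axes.
#' @method autoplot dfa_fluctuation
#' @export
autoplot.dfa_fluctuation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scale, y = .data$fluctuation)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window size n", y = "F(n)") +
    ggplot2::theme_minimal()
}

#' Plot simulation results as estimate-versus-exponent boxplots
#'
#' @param object An `rqa_sim` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot faceting each estimator (rows) by condition (columns),
#'   with boxplots of the per-series estimates at each true exponent.
#' @method autoplot rqa_sim
#' @export
autoplot.rqa_sim <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = factor(.data$true_alpha),
                               y = .data$estimate)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "#aec6e8") +
    ggplot2::facet_grid(estimator ~ condition, scales = "free_y") +
    ggplot2::labs(x = expression(true ~ alpha), y = "estimate") +
    ggplot2::theme_minimal()
}
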