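#' Plot a fitted stop-survival curve over the empirical survival function
#'
#' @param object A [fit_stop_survival()] result.
#' @param ... Unused.
#' @return A ggplot object: the Kaplan-Meier step curve with the fitted
#'   heavy-tailed survival function overlaid, on log-log axes where the
#'   power-law regime appears as a straight line.
#' @export
autoplot.stop_survival_fit <- function(object, ...) {
  km <- object$km
  fitted <- tibble::tibble(
    time_s = exp(seq(log(max(min(km$time_s), 1e-3)), log(max(km$time_s)),
                     length.out = 200))
  )
  fitted$survival <- stop_survival(fitted$time_s, object$params)
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time_s, y = .data$survival)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::geom_line(data = fitted, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Stop duration (s)", y = "Fraction still stopped") +
    ggplot2::theme_minimal()
}

#' Plot daily activity of a simulated condition
#'
#' @param summary A [run_condition()] result (or several bound together).
#' @return A ggplot of the activity index per day with across-run CIs.
#' @export
plot_activity <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$day, y = .data$activity,
                                        colour = .data$condition,
                                        fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$act_lo, ymax = .data$act_hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day", y = "Activity index (fraction of 10-min steps moved)") +
    ggplot2::theme_minimal()
}
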