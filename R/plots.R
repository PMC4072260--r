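#' Bland-Altman plot
#'
#' Differences (test - reference) against the reference, with the bias line
#' and the limits of agreement (mean +/- multiplier * SD) drawn as
#' horizontal lines.
#'
#' @param ba a [bland_altman()] result.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, title = NULL) {
  stopifnot(inherits(ba, "bland_altman_result"))
  df <- data.frame(x = ba$x_values, d = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$mean_difference, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        colour = "steelblue", linetype = "dashed") +
    ggplot2::labs(x = "reference fibrosis (%)",
                  y = "difference, test - reference (%)",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Histogram of Bland-Altman differences
#'
#' @param ba a [bland_altman()] result.
#' @param binwidth histogram bin width in percentage points (default 2).
#' @return A ggplot object.
#' @export
plot_difference_histogram <- function(ba, binwidth = 2) {
  stopifnot(inherits(ba, "bland_altman_result"))
  ggplot2::ggplot(data.frame(d = ba$differences), ggplot2::aes(x = .data$d)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey60", colour = "grey30") +
    ggplot2::labs(x = "difference, test - reference (%)", y = "count") +
    ggplot2::theme_minimal()
}

#' Scatter plot with regression line and 95% confidence band
#'
#' @param reg a [fit_regression()] result.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_regression <- function(reg, title = NULL) {
  stopifnot(inherits(reg, "regression_fit"))
  df <- reg$fit$model
  newx <- seq(min(df$x), max(df$x), length.out = 100)
  band <- predict_band(reg, newx)
  lab <- if (reg$transformed == "ln") "ln(% + offset)" else "fibrosis (%)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$x, ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE, fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = reg$slope, intercept = reg$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = paste("reference", lab), y = paste("method", lab),
                  title = title,
                  subtitle = sprintf("slope %.3f, intercept %.3f, r2 %.3f",
                                     reg$slope, reg$intercept, reg$r_squared)) +
    ggplot2::theme_minimal()
}
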