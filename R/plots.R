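#' Plot a lag-cumulative exposure-response curve
#'
#' Draws the cumulative log-relative-rate (or relative rate) of death
#' against temperature, centered at its minimum, with the MMT marked.
#'
#' @param curve A [reduce_over_lags()] result.
#' @param temps Observed temperatures defining the plotting range
#'   (1st-99th percentiles used).
#' @param mmt Optional [estimate_mmt()] result to annotate.
#' @param rr Plot the relative rate (`exp`) instead of the log rate.
#' @return A ggplot object.
#' @export
plot_cumulative_curve <- function(curve, temps, mmt = NULL, rr = TRUE) {
  temps <- temps[!is.na(temps)]
  lims <- stats::quantile(temps, c(0.01, 0.99))
  grid <- seq(lims[1], lims[2], length.out = 200)
  y <- cumulative_curve(curve, grid)
  y <- y - min(y)
  df <- tibble::tibble(temp = grid,
                       value = if (rr) exp(y) else y)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$temp, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Daily mean temperature (°C)",
                  y = if (rr) "Relative rate (cumulative over lags)"
                      else "Log relative rate") +
    ggplot2::theme_minimal()
  if (!is.null(mmt)) {
    p <- p + ggplot2::geom_vline(xintercept = mmt$mmt, linetype = 2,
                                 colour = "firebrick")
  }
  p
}

#' @rdname plot_cumulative_curve
#' @param object A `reduced_curve`.
#' @param ... Passed to [plot_cumulative_curve()].
#' @exportS3Method ggplot2::autoplot
autoplot.reduced_curve <- function(object, ...) {
  plot_cumulative_curve(object, ...)
}

#' Plot a pooled temporal trajectory
#'
#' Pooled MMT (or MMTP) against the subperiod index with its Wald
#' confidence band and the linear-slope annotation.
#'
#' @param object A [pooled_trajectory()] result.
#' @param ylab Axis label.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trend_summary <- function(object, ylab = "Pooled MMT (°C)", ...) {
  df <- object$trajectory
  lab <- sprintf("LS = %.2f (P = %.2g)", object$slope$estimate,
                 object$slope$p.value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w, y = .data$pooled)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::annotate("text", x = min(df$w), y = max(df$conf.high),
                      label = lab, hjust = 0, vjust = 1, size = 3.4) +
    ggplot2::labs(x = "Subperiod", y = ylab) +
    ggplot2::theme_minimal()
}

#' Histogram of Monte-Carlo MMT samples
#'
#' @param object An [estimate_mmt()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mmt_estimate <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(mmt = object$samples),
                  ggplot2::aes(x = .data$mmt)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mmt, colour = "firebrick") +
    ggplot2::labs(x = "MMT (°C), Monte-Carlo samples", y = "Count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"
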