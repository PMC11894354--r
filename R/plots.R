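#' Bland-Altman plot
#'
#' Per-pair differences against means with the mean difference (solid) and
#' 95% limits of agreement (dashed).
#'
#' @param object An `hrv_bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hrv_bland_altman
#' @export
autoplot.hrv_bland_altman <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = s$mean_diff, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(s$loa_low, s$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of devices", y = "Difference (PPG - ECG)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Missingness-contrast forest plot
#'
#' Estimated difference from the reference dataset per missingness level,
#' with parametric-bootstrap 95% CIs.
#'
#' @param object An `hrv_contrasts` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hrv_contrasts
#' @export
autoplot.hrv_contrasts <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = factor(.data$level), y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = "Missingness level (%)",
                  y = "Difference from reference",
                  title = sprintf("%s (%s)", object$metric, object$activity)) +
    ggplot2::theme_minimal()
}

#' Normal Q-Q plot of a metric distribution
#'
#' @param values Numeric vector (see [qq_points()]).
#' @param title Optional plot title.
#' @return A ggplot with the 45-degree reference line through the quartiles.
#' @export
plot_qq <- function(values, title = NULL) {
  pts <- qq_points(values)
  qs <- quantile(pts$sample, c(0.25, 0.75))
  qt <- qnorm(c(0.25, 0.75))
  slope <- diff(qs) / diff(qt)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$theoretical, y = .data$sample)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(intercept = qs[1] - slope * qt[1], slope = slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "Theoretical quantile", y = "Sample quantile",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Plot an IBI window with its gaps and usable segment
#'
#' @param windows One row of a gap-annotated window tibble ([find_gaps()]).
#' @return A ggplot of the beat series, shaded gap intervals and the usable
#'   segment bounds.
#' @export
plot_window <- function(windows) {
  w <- windows[1, ]
  s <- w$samples[[1]]
  g <- if ("gaps" %in% names(w)) w$gaps[[1]] else NULL
  p <- ggplot2::ggplot(s, ggplot2::aes(x = (.data$timestamp_ms - w$window_start_ms) / 1000,
                                       y = .data$ibi_ms)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "Seconds from window start", y = "IBI (ms)") +
    ggplot2::xlim(0, 300) +
    ggplot2::theme_minimal()
  if (!is.null(g) && nrow(g)) {
    p <- p + ggplot2::annotate(
      "rect",
      xmin = (g$gap_start_ms - w$window_start_ms) / 1000,
      xmax = (g$gap_end_ms - w$window_start_ms) / 1000,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red")
  }
  p
}
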