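# ggplot2 visual summaries.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted tuning curve
#'
#' Draws the fitted DoG or Clifford curve over the full range of relative
#' angles; with `data` supplied, overlays the circular moving average of
#' the raw errors with a standard-error ribbon.
#'
#' @param object A `tuning_fit`.
#' @param data Optional trial data frame (columns `x_prev`,
#'   `residual_error`).
#' @param window_deg Moving-average window for the overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tuning_fit <- function(object, data = NULL, window_deg = 20, ...) {
  grid <- tibble::tibble(x = seq(-180, 180, by = 0.5))
  grid$y <- tuning_curve(object)(grid$x)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(data)) {
    ma <- moving_average(data, window_deg = window_deg)
    p <- p +
      ggplot2::geom_ribbon(
        data = ma,
        ggplot2::aes(x = .data$x, ymin = .data$mean - .data$se,
                     ymax = .data$mean + .data$se),
        inherit.aes = FALSE, fill = "grey80"
      ) +
      ggplot2::geom_line(
        data = ma, ggplot2::aes(x = .data$x, y = .data$mean),
        inherit.aes = FALSE, linewidth = 0.3, colour = "grey40"
      )
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(
      x = "relative angle of previous stimulus (deg)",
      y = "response error (deg)",
      title = sprintf("%s fit, peak-to-peak %.2f deg",
                      object$model, object$peak_to_peak)
    )
}

#' Plot a resampling distribution
#'
#' Histogram of the null (permutation) or bootstrap distribution with the
#' observed statistic marked.
#'
#' @param object A `resample_result`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resample_result <- function(object, bins = 40, ...) {
  df <- tibble::tibble(stat = object$null_or_boot)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "signed peak-to-peak (deg)", y = "count",
                  title = object$kind)
}

#' Plot the variance power-law fit
#'
#' Observed per-delay variances with the fitted power law and the linear
#' comparison fit.
#'
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble::tibble(delay_s = seq(min(pts$delay_s), max(pts$delay_s),
                                       length.out = 200))
  grid$power <- object$scale * (grid$delay_s + object$t_offset)^object$beta
  grid$linear <- object$linear_coef[1L] + object$linear_coef[2L] * grid$delay_s
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$delay_s, y = .data$variance)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$power, colour = "power law")) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$linear, colour = "linear")) +
    ggplot2::labs(x = "memory delay (s)", y = "error variance (deg^2)",
                  colour = NULL,
                  title = sprintf("variance ~ %.2f (delay + %.2f)^%.2f",
                                  object$scale, object$t_offset, object$beta))
}

#' Time course of the serial-dependence amplitude
#'
#' Plots the signed peak-to-peak per condition level (e.g. per memory
#' delay) with bootstrap CIs, from the tuning table returned by
#' [run_analysis()].
#'
#' @param tuning_tbl The `tuning` tibble of a [run_analysis()] result
#'   (optionally filtered to one grouping).
#' @return A ggplot.
#' @export
plot_timecourse <- function(tuning_tbl) {
  df <- dplyr::mutate(tuning_tbl,
                      level_num = suppressWarnings(as.numeric(.data$level)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level_num,
                                   y = .data$peak_to_peak)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~grouping) +
    ggplot2::labs(x = "condition (s)", y = "signed peak-to-peak (deg)")
}
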