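#' Plot a synthesized BCG cycle
#'
#' Base-graphics plot of the force waveform over one cardiac cycle with
#' the systolic window and detected systolic peak marked.
#'
#' @param x a `bcg_waveform`.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.bcg_waveform <- function(x, ...) {
  graphics::plot(x$t, x$F / 1e5, type = "l", lwd = 2,
                 xlab = "time after cycle start [s]",
                 ylab = expression(paste("force [", 10^5, " dyne]")),
                 main = paste("BCG waveform:", x$version), ...)
  graphics::abline(v = x$window, lty = 3, col = "grey50")
  graphics::points(x$systolic_peak_time,
                   max(x$F[x$t >= x$window[1] & x$t <= x$window[2]]) / 1e5,
                   pch = 19, col = "red3")
  graphics::abline(h = 0, col = "grey80")
  invisible(x)
}

#' Bar plot of one metric across the eight model versions
#'
#' @param suite a `suite_result`.
#' @param metric column name of the metric to plot.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot_suite_bar <- function(suite, metric = "LV_EDV_mL", ...) {
  stopifnot(inherits(suite, "suite_result"), metric %in% names(suite))
  vals <- suite[[metric]]
  names(vals) <- sub("idealized_", "", suite$version)
  graphics::barplot(vals, las = 2, ylab = metric,
                    col = ifelse(grepl("male|female", names(vals)),
                                 "grey30", "grey70"), ...)
}
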