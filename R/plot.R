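## Base-graphics figures: the process-variable curve with its stop
## marker, and the two-lot concentration comparison.

#' Plot a process-variable trace
#'
#' Raw and smoothed process variable against time (percent of full
#' scale), with a vertical marker at the stop time when one exists.
#' With `file` set, the plot is written as a PNG and the path returned;
#' otherwise it draws on the current device.
#'
#' @param trace A [process_trace()].
#' @param stop_time Stop time in minutes, or `NA`/`NULL` for none.
#' @param file Optional PNG output path.
#' @param width,height Device size in pixels when writing a file.
#' @param ... Passed to [graphics::plot()].
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_trace <- function(trace, stop_time = NA, file = NULL,
                       width = 800, height = 500, ...) {
  stopifnot(inherits(trace, "process_trace"))
  if (nrow(trace) == 0) stop("empty trace")
  draw <- function() {
    graphics::plot(trace$time_min, trace$raw_percent, type = "l",
                   col = "grey60", lwd = 1,
                   xlab = "time (min)", ylab = "process variable (%)",
                   ylim = c(0, 100), ...)
    graphics::lines(trace$time_min, trace$smoothed_percent,
                    col = "darkblue", lwd = 2)
    if (!is.null(stop_time) && !is.na(stop_time)) {
      graphics::abline(v = stop_time, col = "red", lty = 2)
      graphics::mtext(sprintf("stop: %g min", stop_time), side = 3,
                      adj = 1, col = "red", cex = 0.8)
    }
    graphics::legend("bottomright", legend = c("raw", "smoothed"),
                     col = c("grey60", "darkblue"), lwd = c(1, 2), bty = "n")
  }
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
    draw()
    return(invisible(file))
  }
  draw()
  invisible(NULL)
}

#' Plot a control-vs-treatment lot comparison
#'
#' Both concentration series on common axes with their detected
#' endpoints marked; the panel title reports the rounded percent time
#' reduction.
#'
#' @param control,treatment [concentration_series()] objects.
#' @param comparison The [compare_lots()] result for the two series.
#' @param file Optional PNG output path.
#' @param width,height Device size in pixels when writing a file.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_comparison <- function(control, treatment, comparison, file = NULL,
                            width = 800, height = 500) {
  stopifnot(inherits(comparison, "lot_comparison"))
  draw <- function() {
    ylim <- range(0, control$value, treatment$value)
    graphics::plot(control$time_min, control$value, type = "b", pch = 16,
                   col = "firebrick", ylim = ylim,
                   xlab = "time (min)",
                   ylab = sprintf("concentration (%s)", attr(control, "units")),
                   main = sprintf("decellularization time reduced by ~%d%%",
                                  round(comparison$percent_reduction)))
    graphics::lines(treatment$time_min, treatment$value, type = "b",
                    pch = 17, col = "steelblue")
    graphics::abline(v = comparison$t_control_min, col = "firebrick", lty = 2)
    graphics::abline(v = comparison$t_treatment_min, col = "steelblue", lty = 2)
    graphics::legend("bottomright",
                     legend = c(sprintf("control (endpoint %g min)",
                                        comparison$t_control_min),
                                sprintf("treatment (endpoint %g min)",
                                        comparison$t_treatment_min)),
                     col = c("firebrick", "steelblue"), pch = c(16, 17),
                     bty = "n")
  }
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
    draw()
    return(invisible(file))
  }
  draw()
  invisible(NULL)
}
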