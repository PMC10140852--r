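## Image-based process monitoring: ROI mean grayscale -> percent ->
## Gaussian smoothing -> last-N / k-percent stopping rule.

#' Rectangular region of interest
#'
#' Pixel coordinates are 0-based and half-open: the ROI covers columns
#' `x0 .. x1-1` and rows `y0 .. y1-1`.  The region is fixed once framed
#' and must not change during a run.
#'
#' @param x0,y0 Inclusive top-left corner (0-based).
#' @param x1,y1 Exclusive bottom-right corner.
#' @return An object of class `decell_roi`.
#' @export
#' @examples
#' roi(0, 0, 4, 4)   # the 16 pixels of a 4 x 4 corner block
roi <- function(x0, y0, x1, y1) {
  stopifnot(is.numeric(c(x0, y0, x1, y1)))
  if (x0 < 0 || y0 < 0 || x1 <= x0 || y1 <= y0)
    stop("invalid ROI: need 0 <= x0 < x1 and 0 <= y0 < y1 (0-based, half-open)")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "decell_roi")
}

#' @export
print.decell_roi <- function(x, ...) {
  cat(sprintf("ROI [x %d..%d) x [y %d..%d), %d px (0-based, half-open)\n",
              x$x0, x$x1, x$y0, x$y1, (x$x1 - x$x0) * (x$y1 - x$y0)))
  invisible(x)
}

#' Largest practical ROI inside the phantom's heart ellipse
#'
#' An axis-aligned rectangle centred on the heart with half-sides
#' `shrink` times the ellipse semi-axes.  For `shrink <= 1/sqrt(2)`
#' (default 0.7) the rectangle lies fully inside the ellipse, so every
#' ROI pixel carries dye signal and none is background.
#'
#' @param scene A [phantom_scene()].
#' @param shrink Fraction of each semi-axis used as the ROI half-side.
#' @return A [roi()].
#' @export
heart_roi <- function(scene, shrink = 0.7) {
  stopifnot(inherits(scene, "phantom_scene"), shrink > 0, shrink <= 1 / sqrt(2))
  cx <- scene$heart_center[1]; cy <- scene$heart_center[2]
  a <- scene$heart_semiaxes[1]; b <- scene$heart_semiaxes[2]
  r <- roi(ceiling(cx - shrink * a), ceiling(cy - shrink * b),
           floor(cx + shrink * a), floor(cy + shrink * b))
  mask <- scene_heart_mask(scene)
  if (!all(mask[(r$y0 + 1L):r$y1, (r$x0 + 1L):r$x1]))
    stop("internal error: heart ROI crosses the ellipse boundary")
  r
}

#' Convert a frame to single-channel grayscale
#'
#' Single-channel frames pass through unchanged.  Three-channel (RGB)
#' frames reduce to the green channel: the rig's ~530 nm green backlight
#' places the entire optical signal there, so the green plane carries the
#' measurement and the other channels only add noise.
#'
#' @param frame A `decell_frame` whose `pixels` is a matrix (grayscale)
#'   or a height x width x 3 array (RGB).
#' @return A single-channel `decell_frame`.
#' @export
to_grayscale <- function(frame) {
  stopifnot(inherits(frame, "decell_frame"))
  px <- frame$pixels
  if (is.matrix(px)) return(frame)
  if (is.array(px) && length(dim(px)) == 3L) {
    if (dim(px)[3] != 3L)
      stop("unsupported channel count: expected 1 or 3 channels, got ", dim(px)[3])
    frame$pixels <- px[, , 2L]
    return(frame)
  }
  stop("frame pixels must be a matrix or a 3-channel array")
}

#' ROI mean intensity
#'
#' Exact arithmetic mean of all pixels inside the ROI, computed in double
#' precision (no integer truncation).
#'
#' @param frame A single-channel `decell_frame`.
#' @param roi A [roi()] valid for the frame.
#' @return Mean intensity in `[0, 255]`.
#' @export
mean_intensity <- function(frame, roi) {
  stopifnot(inherits(frame, "decell_frame"), inherits(roi, "decell_roi"))
  px <- frame$pixels
  if (!is.matrix(px)) stop("frame must be single-channel; see to_grayscale()")
  if (roi$x1 > ncol(px) || roi$y1 > nrow(px))
    stop("ROI exceeds frame bounds")
  mean(as.numeric(px[(roi$y0 + 1L):roi$y1, (roi$x0 + 1L):roi$x1]))
}

#' Intensity to percent scale
#'
#' The process variable is displayed as a percentage of full scale
#' (white = 255): `value / 255 * 100`.
#'
#' @param value Intensity value(s) in `[0, 255]`.
#' @return Percent value(s) in `[0, 100]`.
#' @export
to_percent <- function(value) {
  if (any(value < 0 | value > 255)) stop("value must be in [0, 255]")
  value / 255 * 100
}

#' Gaussian smoothing of a 1-D trace
#'
#' Convolves with a discrete Gaussian kernel truncated at 4 sigma
#' (radius `ceiling(4 * sigma)` samples), weights normalised to sum 1.
#' The signal is reflect-padded at both ends (edge-repeating reflection:
#' `x[1], x[1], x[2], ...` mirrored), so a constant trace is returned
#' unchanged and the output has the input's length.
#'
#' @param raw Numeric vector (length >= 1).
#' @param sigma Kernel standard deviation in samples (> 0); default 2.
#' @return Smoothed vector of the same length.
#' @export
smooth_trace <- function(raw, sigma = 2) {
  stopifnot(is.numeric(raw), length(raw) >= 1, sigma > 0)
  r <- as.integer(ceiling(4 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  n <- length(raw)
  # edge-repeating reflection (period 2n) for positions 1-r .. n+r,
  # valid even when the kernel radius exceeds the trace length
  j <- seq.int(1L - r, n + r)
  p <- ((j - 1L) %% (2L * n) + 2L * n) %% (2L * n)
  idx <- ifelse(p < n, p + 1L, 2L * n - p)
  padded <- raw[idx]
  out <- stats::filter(padded, w, sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Stopping rule for the monitored process variable
#'
#' The process is declared complete when the most recent `window_n`
#' smoothed process-variable values show no variation beyond `k_percent`
#' of their own mean: `max - min <= (k/100) * mean` over the window.
#' This is a relative-range reading of the "no variations of more than
#' k%" plateau criterion -- symmetric and scale-free.
#'
#' @param window_n Number of most recent values compared (>= 2);
#'   default 10.
#' @param k_percent Allowed relative range in percent (> 0); default 3.
#' @param smoothing_sigma Gaussian sigma, in samples, applied to the raw
#'   trace before the rule is evaluated (> 0); default 2.
#' @return An object of class `stopping_rule`.
#' @export
stopping_rule <- function(window_n = 10, k_percent = 3.0, smoothing_sigma = 2.0) {
  if (window_n < 2) stop("window_n must be >= 2")
  if (k_percent <= 0) stop("k_percent must be > 0")
  if (smoothing_sigma <= 0) stop("smoothing_sigma must be > 0")
  structure(list(window_n = as.integer(window_n),
                 k_percent = k_percent,
                 smoothing_sigma = smoothing_sigma),
            class = "stopping_rule")
}

#' @export
print.stopping_rule <- function(x, ...) {
  cat(sprintf("Stopping rule: last %d smoothed values within %g%% of window mean (sigma = %g)\n",
              x$window_n, x$k_percent, x$smoothing_sigma))
  invisible(x)
}

#' Process-variable trace
#'
#' Parallel sequences of frame times, raw ROI-mean percentages and their
#' Gaussian-smoothed counterparts.  Both raw and smoothed values are
#' retained so either can be audited against the stop decision.
#'
#' @param times_min Strictly increasing times in minutes.
#' @param raw_percent Raw process variable in `[0, 100]`.
#' @param smoothed_percent Smoothed process variable in `[0, 100]`.
#' @return An object of class `process_trace` (also a data.frame).
#' @export
process_trace <- function(times_min, raw_percent, smoothed_percent) {
  n <- length(times_min)
  if (length(raw_percent) != n || length(smoothed_percent) != n)
    stop("times, raw and smoothed sequences must have equal length")
  if (n > 1 && any(diff(times_min) <= 0))
    stop("times_min must be strictly increasing")
  if (any(raw_percent < 0 | raw_percent > 100))
    stop("raw_percent must be in [0, 100]")
  structure(data.frame(time_min = times_min,
                       raw_percent = raw_percent,
                       smoothed_percent = smoothed_percent),
            class = c("process_trace", "data.frame"))
}

#' @export
print.process_trace <- function(x, ...) {
  cat(sprintf("Process trace: %d frames, t = %g .. %g min, last raw %.2f%% / smoothed %.2f%%\n",
              nrow(x), x$time_min[1], x$time_min[nrow(x)],
              x$raw_percent[nrow(x)], x$smoothed_percent[nrow(x)]))
  invisible(x)
}

#' Evaluate the stopping rule on a trace
#'
#' Returns `FALSE` while fewer than `window_n` samples exist; otherwise
#' `TRUE` iff the range (max - min) of the last `window_n` smoothed
#' values is at most `k_percent/100` times their mean.  Diagnostics
#' report the window range, mean and threshold actually compared.
#'
#' @param trace A [process_trace()].
#' @param rule A [stopping_rule()].
#' @return Logical with attribute `diagnostics` (list: `window_range`,
#'   `window_mean`, `threshold`, `n_available`).
#' @export
should_stop <- function(trace, rule) {
  stopifnot(inherits(trace, "process_trace"), inherits(rule, "stopping_rule"))
  n <- nrow(trace)
  if (n < rule$window_n) {
    return(structure(FALSE, diagnostics = list(
      window_range = NA_real_, window_mean = NA_real_,
      threshold = NA_real_, n_available = n)))
  }
  w <- trace$smoothed_percent[(n - rule$window_n + 1L):n]
  rng <- max(w) - min(w)
  m <- mean(w)
  thr <- rule$k_percent / 100 * m
  structure(rng <= thr, diagnostics = list(
    window_range = rng, window_mean = m, threshold = thr, n_available = n))
}

#' Run the monitoring loop over a frame sequence
#'
#' For each frame in time order: convert to grayscale, take the ROI mean,
#' scale to percent, append to the trace, re-smooth the full trace, and
#' evaluate the stopping rule.  The stop time is the timestamp of the
#' first frame that satisfies the rule (no hysteresis); monitoring ends
#' there, mirroring the automatic process termination on the rig.  If the
#' frames run out without a trigger, the full trace is returned with
#' `stop_time_min = NA` (not an error).
#'
#' Smoothing is recomputed over the whole trace before every evaluation,
#' which avoids the boundary bias of a streaming kernel.
#'
#' @param frames A `frame_series` or a list of `decell_frame`s in time
#'   order.
#' @param roi A [roi()].
#' @param rule A [stopping_rule()].
#' @return An object of class `monitor_run`: list with `trace`
#'   (a [process_trace()]), `stop_time_min` (minutes or `NA`),
#'   `stop_index`, `roi` and `rule`.
#' @export
run_monitor <- function(frames, roi, rule = stopping_rule()) {
  if (inherits(frames, "frame_series")) frames <- frames$frames
  stopifnot(is.list(frames), length(frames) >= 1,
            inherits(roi, "decell_roi"), inherits(rule, "stopping_rule"))
  times <- vapply(frames, function(f) f$timestamp_min, numeric(1))
  if (any(diff(times) <= 0)) stop("frames must be strictly time-ordered")
  raw <- numeric(0)
  stop_time <- NA_real_
  stop_index <- NA_integer_
  used <- 0L
  for (i in seq_along(frames)) {
    g <- to_grayscale(frames[[i]])
    raw <- c(raw, to_percent(mean_intensity(g, roi)))
    used <- i
    sm <- smooth_trace(raw, rule$smoothing_sigma)
    tr <- process_trace(times[seq_len(i)], raw, sm)
    if (isTRUE(as.logical(should_stop(tr, rule)))) {
      stop_time <- times[i]
      stop_index <- i
      break
    }
  }
  sm <- smooth_trace(raw, rule$smoothing_sigma)
  structure(list(trace = process_trace(times[seq_len(used)], raw, sm),
                 stop_time_min = stop_time,
                 stop_index = stop_index,
                 roi = roi, rule = rule),
            class = "monitor_run")
}

#' @export
print.monitor_run <- function(x, ...) {
  print(x$trace)
  if (is.na(x$stop_time_min)) {
    cat("No stop triggered (frames exhausted)\n")
  } else {
    cat(sprintf("Process complete: stop at %g min (frame %d)\n",
                x$stop_time_min, x$stop_index))
  }
  invisible(x)
}

#' @export
plot.monitor_run <- function(x, ...) {
  plot_trace(x$trace, stop_time = x$stop_time_min, ...)
}

#' Normalise a stop time to the perfusion flow rate
#'
#' Reports the total perfusate volume delivered at the stop:
#' `flow (mL/h) * time (min) / 60`.  This makes runs at different flow
#' settings comparable on the clinically relevant axis (solution used).
#'
#' @param stop_time_min Stop time in minutes (> 0).
#' @param flow_rate_mL_per_h Constant pump flow in mL/h (> 0).
#' @return Delivered volume in mL.
#' @export
#' @examples
#' normalize_time_to_flow(60, 50)    # 50 mL
normalize_time_to_flow <- function(stop_time_min, flow_rate_mL_per_h) {
  if (any(stop_time_min <= 0)) stop("stop_time_min must be > 0")
  if (any(flow_rate_mL_per_h <= 0)) stop("flow_rate_mL_per_h must be > 0")
  flow_rate_mL_per_h * stop_time_min / 60
}
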