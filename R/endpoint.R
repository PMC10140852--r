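## Spectrophotometric endpoint analytics: successive differences,
## plateau detection, and control-vs-treatment time comparison.

#' Concentration time series
#'
#' Sampled analyte concentrations against time, typically on a 30-min
#' grid.  The units label (e.g. `"ng/uL"` for nucleic acids, `"mg/mL"`
#' for proteins) is carried verbatim from input and never converted.
#'
#' @param times_min Strictly increasing sample times in minutes.
#' @param values Nonnegative concentrations.
#' @param analyte One of `"dye"`, `"dna"`, `"protein"`.
#' @param units Free-text units label.
#' @return An object of class `concentration_series` (also a data.frame
#'   with columns `time_min`, `value`; `analyte` and `units` are
#'   attributes).
#' @export
concentration_series <- function(times_min, values,
                                 analyte = c("dye", "dna", "protein"),
                                 units = "") {
  analyte <- match.arg(analyte)
  if (length(times_min) != length(values))
    stop("times_min and values must have equal length")
  if (length(times_min) > 1 && any(diff(times_min) <= 0))
    stop("times_min must be strictly increasing")
  if (any(values < 0)) stop("values must be >= 0")
  structure(data.frame(time_min = as.numeric(times_min),
                       value = as.numeric(values)),
            analyte = analyte, units = units,
            class = c("concentration_series", "data.frame"))
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("Concentration series (%s, %s): %d samples, t = %g .. %g min, last value %.4g\n",
              attr(x, "analyte"), attr(x, "units"), nrow(x),
              x$time_min[1], x$time_min[nrow(x)], x$value[nrow(x)]))
  invisible(x)
}

#' Endpoint criteria for the successive-differences method
#'
#' A plateau is declared when `run_length_m` consecutive absolute
#' successive differences all fall below `diff_epsilon` times the
#' series' full range (max - min).  The range-relative threshold makes
#' the rule scale-free; the run length rejects single flat steps.
#'
#' @param diff_epsilon Threshold as a fraction of the series range,
#'   in (0, 1); default 0.02.
#' @param run_length_m Required consecutive qualifying differences
#'   (>= 1); default 3.
#' @return An object of class `endpoint_criteria`.
#' @export
endpoint_criteria <- function(diff_epsilon = 0.02, run_length_m = 3) {
  if (diff_epsilon <= 0 || diff_epsilon >= 1)
    stop("diff_epsilon must be in (0, 1)")
  if (run_length_m < 1) stop("run_length_m must be >= 1")
  structure(list(diff_epsilon = diff_epsilon,
                 run_length_m = as.integer(run_length_m)),
            class = "endpoint_criteria")
}

#' Successive absolute differences
#'
#' The consecutive-differences method: `d_i = |v_i - v_{i-1}|` for each
#' adjacent pair of measurements.  A sustained fall of these differences
#' below a small threshold marks the concentration plateau.
#'
#' @param series A [concentration_series()] with at least 2 samples.
#' @return Numeric vector of length `n - 1`.
#' @export
#' @examples
#' s <- concentration_series(c(0, 30, 60), c(1, 3, 6), "dna", "ng/uL")
#' successive_differences(s)   # 2, 3
successive_differences <- function(series) {
  stopifnot(inherits(series, "concentration_series"))
  if (nrow(series) < 2) stop("need at least 2 samples")
  abs(diff(series$value))
}

#' Detect the concentration plateau (process endpoint)
#'
#' Scans the successive absolute differences for the first run of
#' `run_length_m` values all at most `diff_epsilon * (max - min)` of the
#' series.  The endpoint is the time of the later sample of the first
#' qualifying difference -- the moment the series enters its plateau.
#' Returns an endpoint of `NA` when no such run exists.  A degenerate,
#' perfectly flat series (max = min) is flagged `flat_series` and, with
#' all differences zero, yields the second sample's time.
#'
#' Absolute (not signed) differences are used, so small non-monotone
#' noise near the plateau does not defeat the rule.  No smoothing is
#' applied by default; set `presmooth_sigma` to Gaussian-smooth the
#' values first (off by default -- smoothing belongs to the image trace,
#' not the sampled concentrations).
#'
#' @param series A [concentration_series()] with at least
#'   `run_length_m + 1` samples.
#' @param criteria An [endpoint_criteria()].
#' @param presmooth_sigma Optional Gaussian sigma (samples) applied to
#'   the values before differencing; `NULL` (default) for none.
#' @return An object of class `endpoint_result`: list with
#'   `endpoint_time_min` (or `NA`), `diffs`, `epsilon_abs`, `criteria`,
#'   `flat_series`, and the `analyte` label.
#' @export
detect_endpoint <- function(series, criteria = endpoint_criteria(),
                            presmooth_sigma = NULL) {
  stopifnot(inherits(series, "concentration_series"),
            inherits(criteria, "endpoint_criteria"))
  if (nrow(series) < criteria$run_length_m + 1)
    stop("need at least run_length_m + 1 samples")
  values <- series$value
  if (!is.null(presmooth_sigma)) values <- smooth_trace(values, presmooth_sigma)
  d <- abs(diff(values))
  rng <- max(values) - min(values)
  flat <- rng == 0
  eps_abs <- criteria$diff_epsilon * rng
  m <- criteria$run_length_m
  ok <- d <= eps_abs
  endpoint <- NA_real_
  # first index i with ok[i..i+m-1] all TRUE; endpoint = time of the
  # later sample of difference i (series row i + 1)
  if (length(ok) >= m) {
    runs <- which(stats::filter(as.numeric(ok), rep(1, m), sides = 1) == m) - m + 1L
    if (length(runs) > 0) endpoint <- series$time_min[runs[1] + 1L]
  }
  structure(list(endpoint_time_min = endpoint, diffs = d,
                 epsilon_abs = eps_abs, criteria = criteria,
                 flat_series = flat, analyte = attr(series, "analyte")),
            class = "endpoint_result")
}

#' @export
print.endpoint_result <- function(x, ...) {
  if (is.na(x$endpoint_time_min)) {
    cat(sprintf("No plateau detected (%s): no run of %d differences <= %.4g\n",
                x$analyte, x$criteria$run_length_m, x$epsilon_abs))
  } else {
    cat(sprintf("Endpoint (%s): %g min  [threshold %.4g, run length %d%s]\n",
                x$analyte, x$endpoint_time_min, x$epsilon_abs,
                x$criteria$run_length_m,
                if (x$flat_series) ", flat series" else ""))
  }
  invisible(x)
}

#' Percent reduction of decellularization time
#'
#' `(t_control - t_treatment) / t_control * 100`, full precision.
#' Rounding to an integer percent for presentation is left to the
#' caller (e.g. `round()`).
#'
#' @param t_control_min Control endpoint time in minutes (> 0).
#' @param t_treatment_min Treatment endpoint time in minutes (>= 0).
#' @return Percent reduction (negative if the treatment is slower).
#' @export
#' @examples
#' percent_reduction(600, 420)   # 30
#' round(percent_reduction(630, 450))   # 29
percent_reduction <- function(t_control_min, t_treatment_min) {
  if (any(t_control_min <= 0)) stop("t_control_min must be > 0")
  if (any(t_treatment_min < 0)) stop("t_treatment_min must be >= 0")
  (t_control_min - t_treatment_min) / t_control_min * 100
}

#' Compare decellularization endpoints between two lots
#'
#' Detects the plateau endpoint of a control and a treatment series and
#' assembles the percent time reduction.  Fails with an explicit error
#' naming the lot if either series shows no plateau.
#'
#' @param control,treatment [concentration_series()] objects.
#' @param criteria An [endpoint_criteria()] applied to both.
#' @return An object of class `lot_comparison`: list with
#'   `t_control_min`, `t_treatment_min`, `percent_reduction`, and the
#'   two `endpoint_result`s.
#' @export
compare_lots <- function(control, treatment, criteria = endpoint_criteria()) {
  ec <- detect_endpoint(control, criteria)
  et <- detect_endpoint(treatment, criteria)
  if (is.na(ec$endpoint_time_min))
    stop("no plateau detected in the control lot")
  if (is.na(et$endpoint_time_min))
    stop("no plateau detected in the treatment lot")
  structure(list(t_control_min = ec$endpoint_time_min,
                 t_treatment_min = et$endpoint_time_min,
                 percent_reduction = percent_reduction(ec$endpoint_time_min,
                                                       et$endpoint_time_min),
                 control = ec, treatment = et),
            class = "lot_comparison")
}

#' @export
print.lot_comparison <- function(x, ...) {
  cat(sprintf("Lot comparison: control endpoint %g min, treatment endpoint %g min\n",
              x$t_control_min, x$t_treatment_min))
  cat(sprintf("  decellularization time reduced by %.2f%% (~%d%%)\n",
              x$percent_reduction, round(x$percent_reduction)))
  invisible(x)
}
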