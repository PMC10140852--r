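## Analytic stop-time oracle and inverse calibration.  The rig's dye
## reservoir volume and the tissue release time constants are free
## parameters; these helpers solve for them from a target endpoint time,
## which is how benchmark fixtures anchored at known endpoints are built.

#' Predicted stop time from the closed-form trace
#'
#' Evaluates the noise-free process variable directly from the Gompertz
#' closed form \eqn{P(t) = I_0 10^{-\epsilon l c_0 e^{-Qt/(60V)}}/255
#' \cdot 100} on the frame grid and applies exactly the monitoring
#' semantics of [run_monitor()] (grow the trace frame by frame, re-smooth,
#' evaluate the stopping rule).  No images are rendered, so this serves
#' both as a fast planner and as the analytic oracle a rendered run must
#' match to within one frame interval.
#'
#' @param model A [dilution_model()].
#' @param backlight_intensity Backlight `I0` (0-255).
#' @param rule A [stopping_rule()].
#' @param frame_interval_min Minutes between frames.
#' @param max_frames Frames available before giving up.
#' @return Stop time in minutes, or `NA` if the rule never triggers.
#' @export
predict_stop_time <- function(model, backlight_intensity = 250,
                              rule = stopping_rule(),
                              frame_interval_min = 5, max_frames = 200) {
  stopifnot(inherits(model, "dilution_model"), inherits(rule, "stopping_rule"))
  times <- (seq_len(max_frames) - 1) * frame_interval_min
  conc <- dye_concentration(model, times)
  raw <- to_percent(backlight_intensity *
                      transmittance(conc, model$optical_depth_coeff))
  first_trigger_time(times, raw, rule)
}

# streaming evaluation shared by the oracle: first time the rule fires
# when the trace is grown sample by sample and re-smoothed each step
first_trigger_time <- function(times, raw, rule) {
  for (i in seq_along(raw)) {
    if (i < rule$window_n) next
    sm <- smooth_trace(raw[seq_len(i)], rule$smoothing_sigma)
    tr <- process_trace(times[seq_len(i)], raw[seq_len(i)], sm)
    if (isTRUE(as.logical(should_stop(tr, rule)))) return(times[i])
  }
  NA_real_
}

#' Calibrate the reservoir volume to a target stop time
#'
#' Solves for the dilution volume `V` (at fixed flow, dye load and
#' optics) such that the monitored run stops exactly at
#' `target_stop_min`.  Larger volumes dilute slower and stop later, so
#' the stop time is a nondecreasing staircase in `V`; a bisection on
#' that staircase finds a volume whose predicted stop equals the target
#' (which must lie on the frame grid).  By default the prediction uses
#' the closed-form oracle; supply `evaluate` to calibrate against any
#' other stop-time function of the model (e.g. a fully rendered run).
#'
#' @param target_stop_min Desired stop time, a multiple of the frame
#'   interval.
#' @param flow_rate_mL_per_h,initial_concentration,optical_depth_coeff
#'   Fixed dilution-model parameters.
#' @param backlight_intensity Backlight `I0`.
#' @param rule A [stopping_rule()].
#' @param frame_interval_min Minutes between frames.
#' @param evaluate Optional function `(dilution_model) -> stop time` used
#'   in place of [predict_stop_time()].
#' @return The calibrated [dilution_model()].
#' @export
calibrate_dilution <- function(target_stop_min,
                               flow_rate_mL_per_h = 50,
                               initial_concentration = 1,
                               optical_depth_coeff = 2.5,
                               backlight_intensity = 250,
                               rule = stopping_rule(),
                               frame_interval_min = 5,
                               evaluate = NULL) {
  stopifnot(target_stop_min > 0)
  max_frames <- ceiling(target_stop_min / frame_interval_min) + 5L * rule$window_n
  make <- function(V) dilution_model(V, flow_rate_mL_per_h,
                                     initial_concentration, optical_depth_coeff)
  f <- if (is.null(evaluate)) {
    function(V) predict_stop_time(make(V), backlight_intensity, rule,
                                  frame_interval_min, max_frames)
  } else {
    function(V) evaluate(make(V))
  }
  # The stop time first rises with V (slower dilution -> later plateau),
  # then collapses: once dilution is so slow that the initial dark trace
  # is itself flat to within k%, the rule fires as soon as the window
  # fills.  Bracket the target inside the rising branch by geometric
  # scan, then bisect.
  lo <- target_stop_min * flow_rate_mL_per_h / 60000   # far too small
  s_lo <- f(lo)
  if (is.na(s_lo)) s_lo <- Inf
  if (s_lo >= target_stop_min)
    stop("calibration bracket failed: smallest volume already stops at ", s_lo)
  hi <- lo
  s_hi <- s_lo
  repeat {
    cand <- hi * 1.3
    s <- f(cand)
    if (is.na(s)) s <- Inf
    if (is.finite(s) && s < s_hi / 2)
      stop("target stop time unreachable: rule fires on the initial ",
           "plateau (at ", s, " min) before reaching ", target_stop_min, " min")
    lo <- hi
    hi <- cand
    s_hi <- s
    if (s_hi >= target_stop_min) break
    if (hi > 1e6) stop("calibration bracket failed: no volume reaches ",
                       target_stop_min, " min")
  }
  for (iter in 1:40) {
    mid <- sqrt(lo * hi)
    s <- f(mid)
    if (is.na(s)) s <- Inf
    if (s >= target_stop_min) hi <- mid else lo <- mid
    if (hi / lo < 1 + 1e-5) break
  }
  # 8-bit rounding makes the stop staircase locally non-monotone (a
  # volume step can shift the trigger by a frame either way), so finish
  # with a fine multiplicative scan around the bisection point
  offsets <- c(0, rep(seq_len(40), each = 2) * c(1, -1)) * 1e-3
  for (off in offsets) {
    V <- hi * (1 + off)
    s <- f(V)
    if (!is.na(s) && isTRUE(all.equal(s, target_stop_min)))
      return(make(V))
  }
  stop("calibration failed near volume ", signif(hi, 6),
       " mL: no volume found whose run stops at ", target_stop_min, " min")
}

#' Predicted plateau endpoint for a noise-free release series
#'
#' Samples the saturating-exponential release curve on the given grid
#' and runs the successive-differences detector; the noise-free
#' reference against which noisy replicates are judged.
#'
#' @param model A [release_model()] (noise ignored).
#' @param interval_min,duration_min Sampling grid.
#' @param criteria An [endpoint_criteria()].
#' @return Endpoint time in minutes, or `NA`.
#' @export
predict_release_endpoint <- function(model, interval_min = 30,
                                     duration_min = 720,
                                     criteria = endpoint_criteria()) {
  times <- seq(0, duration_min, by = interval_min)
  s <- concentration_series(times, release_concentration(model, times),
                            analyte = model$analyte_label)
  detect_endpoint(s, criteria)$endpoint_time_min
}

#' Calibrate a release time constant to a target endpoint
#'
#' Solves for tau such that the noise-free successive-differences
#' endpoint of \eqn{C_\infty(1 - e^{-t/\tau})} sampled every
#' `interval_min` minutes lands exactly on `target_endpoint_min`.
#' Slower release (larger tau) plateaus later, so the endpoint is a
#' nondecreasing staircase in tau; bisection locates the target step and
#' the returned tau is the geometric centre of that step, keeping the
#' fixture as far from the detection boundary as the target allows.
#'
#' @param target_endpoint_min Desired endpoint, a multiple of the
#'   sampling interval.
#' @param plateau_concentration Plateau level (units immaterial to the
#'   scale-free detector).
#' @param analyte_label Analyte tag for the resulting model.
#' @param interval_min,duration_min Sampling grid; the duration must
#'   extend at least `run_length_m` intervals past the target.
#' @param criteria An [endpoint_criteria()].
#' @return The calibrated [release_model()] (noise_sd = 0).
#' @export
calibrate_release <- function(target_endpoint_min,
                              plateau_concentration = 118,
                              analyte_label = "dna",
                              interval_min = 30, duration_min = 720,
                              criteria = endpoint_criteria()) {
  stopifnot(target_endpoint_min > 0,
            duration_min >= target_endpoint_min +
              criteria$run_length_m * interval_min)
  make <- function(tau) release_model(plateau_concentration, tau,
                                      noise_sd = 0, analyte_label = analyte_label)
  f <- function(tau) {
    e <- predict_release_endpoint(make(tau), interval_min, duration_min, criteria)
    if (is.na(e)) Inf else e
  }
  bisect <- function(lo, hi, reach) {
    # smallest tau (within tolerance) whose endpoint is >= reach
    for (iter in 1:60) {
      mid <- sqrt(lo * hi)
      if (f(mid) >= reach) hi <- mid else lo <- mid
      if (hi / lo < 1 + 1e-12) break
    }
    hi
  }
  lo <- interval_min / 50
  hi <- duration_min * 2
  if (!(f(lo) < target_endpoint_min && f(hi) >= target_endpoint_min))
    stop("calibration bracket failed for target ", target_endpoint_min)
  band_lo <- bisect(lo, hi, target_endpoint_min)   # step's lower edge
  if (f(hi) > target_endpoint_min) {
    band_hi <- bisect(band_lo, hi, target_endpoint_min + interval_min / 2)
  } else {
    band_hi <- hi
  }
  model <- make(sqrt(band_lo * band_hi))
  achieved <- f(model$time_constant_min)
  if (!isTRUE(all.equal(achieved, target_endpoint_min)))
    stop("calibration failed: achieved endpoint ", achieved,
         " min, target ", target_endpoint_min, " min")
  model
}
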