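## Optical phantom: constant-flow dye dilution viewed through Beer-Lambert
## optics, plus saturating release kinetics for the sampled analytes.

#' Constant-flow dilution model of the dye reservoir
#'
#' A single well-stirred compartment of volume `V` is flushed at constant
#' flow `Q`, so the dye concentration decays exponentially:
#' \deqn{c(t) = c_0 \exp(-Q t / (60 V))}
#' with `Q` in mL/h and `t` in minutes (the factor 60 converts hours to
#' minutes).  The lumped optical depth coefficient is the product
#' \eqn{\epsilon l} of molar absorptivity and path length per unit
#' concentration, so absorbance is `optical_depth_coeff * c`.
#'
#' @param reservoir_volume_mL Compartment volume in mL (> 0).
#' @param flow_rate_mL_per_h Perfusion flow in mL/h (> 0); the rig's
#'   clinical syringe-pump default is 50 mL/h.
#' @param initial_concentration Dye concentration at t = 0, arbitrary
#'   units (> 0).
#' @param optical_depth_coeff Absorbance per unit concentration (>= 0).
#' @return An object of class `dilution_model`.
#' @seealso [dye_concentration()], [transmittance()],
#'   [simulate_discoloration_run()]
#' @export
#' @examples
#' m <- dilution_model(reservoir_volume_mL = 50, initial_concentration = 1,
#'                     optical_depth_coeff = 2)
#' dye_concentration(m, 60)
dilution_model <- function(reservoir_volume_mL,
                           flow_rate_mL_per_h = 50,
                           initial_concentration = 1,
                           optical_depth_coeff = 2) {
  stopifnot(is.numeric(reservoir_volume_mL), length(reservoir_volume_mL) == 1L,
            is.numeric(flow_rate_mL_per_h), length(flow_rate_mL_per_h) == 1L,
            is.numeric(initial_concentration), length(initial_concentration) == 1L,
            is.numeric(optical_depth_coeff), length(optical_depth_coeff) == 1L)
  if (reservoir_volume_mL <= 0) stop("reservoir_volume_mL must be > 0")
  if (flow_rate_mL_per_h <= 0) stop("flow_rate_mL_per_h must be > 0")
  if (initial_concentration <= 0) stop("initial_concentration must be > 0")
  if (optical_depth_coeff < 0) stop("optical_depth_coeff must be >= 0")
  structure(list(reservoir_volume_mL = reservoir_volume_mL,
                 flow_rate_mL_per_h = flow_rate_mL_per_h,
                 initial_concentration = initial_concentration,
                 optical_depth_coeff = optical_depth_coeff),
            class = "dilution_model")
}

#' @export
print.dilution_model <- function(x, ...) {
  cat("Well-stirred dilution model\n")
  cat(sprintf("  volume: %g mL   flow: %g mL/h   c0: %g   eps*l: %g\n",
              x$reservoir_volume_mL, x$flow_rate_mL_per_h,
              x$initial_concentration, x$optical_depth_coeff))
  half <- 60 * x$reservoir_volume_mL * log(2) / x$flow_rate_mL_per_h
  cat(sprintf("  dilution half-life: %.1f min\n", half))
  invisible(x)
}

#' Dye concentration at a given time
#'
#' Evaluates the exponential-dilution trajectory
#' \eqn{c(t) = c_0 e^{-Qt/(60V)}}; strictly decreasing for positive flow.
#'
#' @param model A [dilution_model()].
#' @param t_min Time(s) in minutes, >= 0 (vectorised).
#' @return Concentration(s) in `(0, c0]`.
#' @export
dye_concentration <- function(model, t_min) {
  stopifnot(inherits(model, "dilution_model"), is.numeric(t_min))
  if (any(t_min < 0)) stop("t_min must be >= 0")
  rate <- model$flow_rate_mL_per_h / (60 * model$reservoir_volume_mL)
  model$initial_concentration * exp(-rate * t_min)
}

#' Beer-Lambert transmittance
#'
#' Fraction of backlight transmitted through the dye:
#' \eqn{T = 10^{-\epsilon l c}}, the Beer-Lambert law with absorbance
#' `optical_depth_coeff * concentration`.
#'
#' @param concentration Dye concentration(s), >= 0.
#' @param optical_depth_coeff Absorbance per unit concentration, >= 0.
#' @return Transmittance in `(0, 1]`.
#' @export
#' @examples
#' transmittance(1, 1)        # one absorbance unit -> 0.1
#' transmittance(0, 5)        # no dye -> full transmission
transmittance <- function(concentration, optical_depth_coeff) {
  stopifnot(is.numeric(concentration), is.numeric(optical_depth_coeff))
  if (any(concentration < 0)) stop("concentration must be >= 0")
  if (any(optical_depth_coeff < 0)) stop("optical_depth_coeff must be >= 0")
  10^(-optical_depth_coeff * concentration)
}

#' Phantom scene geometry and camera model
#'
#' Describes the rendered view of the dye-filled simulated heart: frame
#' size, an axis-aligned ellipse marking the heart, the green backlight
#' intensity `I0` seen through a fully clear heart, the background level
#' outside the heart, and per-pixel Gaussian sensor noise.  Rendering is
#' single-channel because the rig's ~530 nm green backlight puts all
#' optical signal into the green channel.
#'
#' @param width_px,height_px Frame size in pixels (defaults 1024 x 768).
#' @param heart_center Numeric (cx, cy) in pixel coordinates; default
#'   frame centre.
#' @param heart_semiaxes Numeric (a, b) ellipse semi-axes in pixels;
#'   default 30% of each dimension.
#' @param backlight_intensity Intensity `I0` through zero dye, 0-255.
#' @param background_intensity Intensity outside the heart, 0-255.
#' @param pixel_noise_sd Per-pixel additive Gaussian noise sd (>= 0);
#'   default 2.0, typical sensor noise.
#' @param seed Integer seed used by [simulate_discoloration_run()].
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(width_px = 1024, height_px = 768,
                          heart_center = c(width_px / 2, height_px / 2),
                          heart_semiaxes = c(0.3 * width_px, 0.3 * height_px),
                          backlight_intensity = 250,
                          background_intensity = 30,
                          pixel_noise_sd = 2.0,
                          seed = 1L) {
  stopifnot(width_px >= 1, height_px >= 1,
            length(heart_center) == 2L, length(heart_semiaxes) == 2L,
            all(heart_semiaxes > 0), pixel_noise_sd >= 0)
  if (backlight_intensity < 0 || backlight_intensity > 255)
    stop("backlight_intensity must be in [0, 255]")
  if (background_intensity < 0 || background_intensity > 255)
    stop("background_intensity must be in [0, 255]")
  if (heart_center[1] - heart_semiaxes[1] < 0 ||
      heart_center[1] + heart_semiaxes[1] > width_px ||
      heart_center[2] - heart_semiaxes[2] < 0 ||
      heart_center[2] + heart_semiaxes[2] > height_px)
    stop("heart_region must lie fully within the frame")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 heart_center = as.numeric(heart_center),
                 heart_semiaxes = as.numeric(heart_semiaxes),
                 backlight_intensity = backlight_intensity,
                 background_intensity = background_intensity,
                 pixel_noise_sd = pixel_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("Phantom scene %d x %d px, heart ellipse at (%g, %g), semi-axes (%g, %g)\n",
              x$width_px, x$height_px, x$heart_center[1], x$heart_center[2],
              x$heart_semiaxes[1], x$heart_semiaxes[2]))
  cat(sprintf("  I0 = %g, background = %g, pixel noise sd = %g, seed = %d\n",
              x$backlight_intensity, x$background_intensity,
              x$pixel_noise_sd, x$seed))
  invisible(x)
}

# logical mask of pixels inside the heart ellipse (rows = y, cols = x);
# pixel centres at (x + 0.5, y + 0.5) in 0-based coordinates
scene_heart_mask <- function(scene) {
  x <- (seq_len(scene$width_px) - 0.5 - scene$heart_center[1]) / scene$heart_semiaxes[1]
  y <- (seq_len(scene$height_px) - 0.5 - scene$heart_center[2]) / scene$heart_semiaxes[2]
  outer(y^2, x^2, `+`) <= 1
}

#' Render one phantom frame
#'
#' Pixels inside the heart ellipse take `round(I0 * T)` where `T` is the
#' Beer-Lambert transmittance of the current dye concentration; pixels
#' outside take the background intensity.  Per-pixel Gaussian noise (sd
#' from the scene) is then added, and the result is rounded and clipped to
#' the 8-bit range.  Noise is drawn from R's current RNG stream; seed it
#' (or use [simulate_discoloration_run()], which seeds from the scene)
#' for reproducibility.
#'
#' @param scene A [phantom_scene()].
#' @param concentration Current dye concentration (>= 0).
#' @param optical_depth_coeff Absorbance per unit concentration (>= 0).
#' @param timestamp_min Frame timestamp in minutes.
#' @return A `decell_frame`: list with integer `pixels`
#'   (height x width matrix, 0-255) and `timestamp_min`.
#' @export
render_frame <- function(scene, concentration, optical_depth_coeff,
                         timestamp_min = 0) {
  stopifnot(inherits(scene, "phantom_scene"))
  tr <- transmittance(concentration, optical_depth_coeff)
  mask <- scene_heart_mask(scene)
  px <- matrix(scene$background_intensity,
               nrow = scene$height_px, ncol = scene$width_px)
  px[mask] <- round(scene$backlight_intensity * tr)
  if (scene$pixel_noise_sd > 0)
    px <- px + stats::rnorm(length(px), sd = scene$pixel_noise_sd)
  px <- pmin(pmax(round(px), 0), 255)
  storage.mode(px) <- "integer"
  new_frame(px, timestamp_min)
}

new_frame <- function(pixels, timestamp_min) {
  if (timestamp_min < 0) stop("timestamp_min must be >= 0")
  structure(list(pixels = pixels, timestamp_min = timestamp_min),
            class = "decell_frame")
}

#' @export
print.decell_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Frame %d x %d px at t = %g min (mean %.2f)\n",
              d[2], d[1], x$timestamp_min, mean(x$pixels)))
  invisible(x)
}

#' Simulate a full discoloration run
#'
#' Renders `max_frames` frames at times `0, dt, 2*dt, ...` while the dye
#' dilutes according to `model`.  Alongside the frames, a ground-truth log
#' records the true concentration and the noise-free in-heart mean
#' intensity \eqn{I_0 10^{-\epsilon l c_0 e^{-Qt/(60V)}}} at each frame --
#' a Gompertz curve, which is the analytic oracle the monitored trace
#' must reproduce.
#'
#' @param scene A [phantom_scene()]; its `seed` seeds the pixel noise.
#' @param model A [dilution_model()].
#' @param frame_interval_min Minutes between frames (> 0).
#' @param max_frames Number of frames (>= 1).  A warning is issued below
#'   10 frames, the default stopping-rule window.
#' @return A `frame_series`: list of `frames` (each a `decell_frame`),
#'   `times_min`, and `ground_truth` (data.frame with `time_min`,
#'   `concentration`, `true_mean`).
#' @export
simulate_discoloration_run <- function(scene, model, frame_interval_min = 5,
                                       max_frames = 60) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(model, "dilution_model"),
            frame_interval_min > 0, max_frames >= 1)
  if (max_frames < 10)
    warning("max_frames below 10: shorter than the default stopping-rule window")
  times <- (seq_len(max_frames) - 1) * frame_interval_min
  conc <- dye_concentration(model, times)
  true_mean <- scene$backlight_intensity *
    transmittance(conc, model$optical_depth_coeff)
  set.seed(scene$seed)
  frames <- lapply(seq_along(times), function(i)
    render_frame(scene, conc[i], model$optical_depth_coeff, times[i]))
  structure(list(frames = frames, times_min = times,
                 ground_truth = data.frame(time_min = times,
                                           concentration = conc,
                                           true_mean = true_mean)),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("Frame series: %d frames, t = %g .. %g min\n",
              length(x$frames), min(x$times_min), max(x$times_min)))
  invisible(x)
}

#' Saturating release model for a sampled analyte
#'
#' Cell lysis releases DNA and protein into the chamber fluid; their
#' concentration rises and levels off at a plateau once the tissue is
#' exhausted.  The model is a saturating exponential
#' \deqn{C(t) = C_\infty (1 - e^{-t/\tau})}
#' with plateau `plateau_concentration` and time constant
#' `time_constant_min`.  Measurement noise is additive Gaussian with sd
#' `noise_sd`, truncated at zero when sampling.
#'
#' @param plateau_concentration Asymptotic concentration (> 0), in the
#'   analyte's units (e.g. ng/uL for DNA, mg/mL for protein; the unit
#'   label is carried verbatim, never converted).
#' @param time_constant_min Time constant tau in minutes (> 0).
#' @param noise_sd Measurement noise sd (>= 0), same units as the plateau.
#' @param analyte_label One of `"dye"`, `"dna"`, `"protein"`.
#' @return An object of class `release_model`.
#' @export
release_model <- function(plateau_concentration, time_constant_min,
                          noise_sd = 0, analyte_label = c("dye", "dna", "protein")) {
  analyte_label <- match.arg(analyte_label)
  if (plateau_concentration <= 0) stop("plateau_concentration must be > 0")
  if (time_constant_min <= 0) stop("time_constant_min must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(plateau_concentration = plateau_concentration,
                 time_constant_min = time_constant_min,
                 noise_sd = noise_sd,
                 analyte_label = analyte_label),
            class = "release_model")
}

#' @export
print.release_model <- function(x, ...) {
  cat(sprintf("Release model (%s): plateau %g, tau %g min, noise sd %g\n",
              x$analyte_label, x$plateau_concentration,
              x$time_constant_min, x$noise_sd))
  invisible(x)
}

#' Analyte concentration released by time t
#'
#' Evaluates \eqn{C(t) = C_\infty (1 - e^{-t/\tau})}: zero at t = 0,
#' monotone increasing, approaching the plateau.
#'
#' @param model A [release_model()].
#' @param t_min Time(s) in minutes, >= 0 (vectorised).
#' @return Concentration(s) in `[0, plateau)`.
#' @export
release_concentration <- function(model, t_min) {
  stopifnot(inherits(model, "release_model"), is.numeric(t_min))
  if (any(t_min < 0)) stop("t_min must be >= 0")
  model$plateau_concentration * (1 - exp(-t_min / model$time_constant_min))
}

#' Simulate periodic chamber sampling
#'
#' Emulates the manual sampling protocol: a small aliquot drawn from the
#' decellularization chamber every `interval_min` minutes (default 30)
#' and measured spectrophotometrically.  Samples sit at
#' `0, interval, 2*interval, ...` up to `duration_min`; Gaussian noise of
#' sd `model$noise_sd` is added and truncated at zero (concentrations
#' cannot be negative).
#'
#' @param model A [release_model()].
#' @param interval_min Sampling interval in minutes (> 0), default 30.
#' @param duration_min Total duration (>= interval_min).
#' @param seed Integer seed for the measurement noise.
#' @param units_label Free-text units carried on the series (e.g.
#'   `"ng/uL"`); defaults by analyte.
#' @return A [concentration_series()].
#' @export
simulate_sampling <- function(model, interval_min = 30, duration_min,
                              seed = 1L, units_label = NULL) {
  stopifnot(inherits(model, "release_model"),
            interval_min > 0, duration_min >= interval_min)
  if (is.null(units_label))
    units_label <- switch(model$analyte_label,
                          dna = "ng/uL", protein = "mg/mL", dye = "a.u.")
  times <- seq(0, duration_min, by = interval_min)
  values <- release_concentration(model, times)
  if (model$noise_sd > 0) {
    set.seed(as.integer(seed))
    values <- pmax(values + stats::rnorm(length(values), sd = model$noise_sd), 0)
  }
  concentration_series(times, values, analyte = model$analyte_label,
                       units = units_label)
}
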