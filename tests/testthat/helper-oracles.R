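# Independent brute-force references and small fixture builders.
# These deliberately re-derive each quantity with naive loops so the
# package implementations are checked against a separate route.

# mean of an ROI by explicit double loop over pixels
bf_roi_mean <- function(pixels, x0, y0, x1, y1) {
  total <- 0
  count <- 0
  for (yy in (y0 + 1):y1) {
    for (xx in (x0 + 1):x1) {
      total <- total + as.numeric(pixels[yy, xx])
      count <- count + 1
    }
  }
  total / count
}

# stopping rule re-evaluated literally from its definition
bf_should_stop <- function(smoothed, window_n, k_percent) {
  n <- length(smoothed)
  if (n < window_n) return(FALSE)
  w <- smoothed[(n - window_n + 1):n]
  (max(w) - min(w)) <= k_percent / 100 * mean(w)
}

# endpoint by scanning every candidate run start with explicit loops
bf_detect_endpoint <- function(times, values, diff_epsilon, run_length_m) {
  d <- numeric(length(values) - 1)
  for (i in 2:length(values)) d[i - 1] <- abs(values[i] - values[i - 1])
  eps_abs <- diff_epsilon * (max(values) - min(values))
  n_d <- length(d)
  if (n_d < run_length_m) return(NA_real_)
  for (i in 1:(n_d - run_length_m + 1)) {
    all_ok <- TRUE
    for (j in i:(i + run_length_m - 1)) {
      if (d[j] > eps_abs) { all_ok <- FALSE; break }
    }
    if (all_ok) return(times[i + 1])
  }
  NA_real_
}

# uniform-intensity frame helper
uniform_frame <- function(value, t_min, w = 8, h = 6) {
  px <- matrix(as.integer(value), nrow = h, ncol = w)
  structure(list(pixels = px, timestamp_min = t_min), class = "decell_frame")
}

small_scene <- function(noise = 0, seed = 1L, w = 32, h = 24, I0 = 250) {
  phantom_scene(width_px = w, height_px = h, backlight_intensity = I0,
                pixel_noise_sd = noise, seed = seed)
}
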