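test_that("dye dilution follows the exponential closed form", {
  m <- dilution_model(reservoir_volume_mL = 50, flow_rate_mL_per_h = 50,
                      initial_concentration = 1, optical_depth_coeff = 2)
  expect_equal(dye_concentration(m, 0), 1)
  # one mean residence time: c0 * exp(-1)
  expect_equal(dye_concentration(m, 60), exp(-1), tolerance = 1e-12)
  # half-life identity t_1/2 = 60 V ln2 / Q
  t_half <- 60 * 50 * log(2) / 50
  expect_equal(dye_concentration(m, t_half), 0.5, tolerance = 1e-12)
  expect_error(dye_concentration(m, -1), "t_min")
})

test_that("dilution and release trajectories are monotone on dense grids", {
  set.seed(11)
  t_grid <- seq(0, 800, by = 0.5)
  for (i in 1:5) {
    dm <- dilution_model(runif(1, 10, 300), runif(1, 10, 120),
                         runif(1, 0.5, 3), runif(1, 0.5, 4))
    expect_true(all(diff(dye_concentration(dm, t_grid)) < 0))
    rm_ <- release_model(runif(1, 50, 200), runif(1, 30, 400))
    expect_true(all(diff(release_concentration(rm_, t_grid)) > 0))
  }
})

test_that("transmittance obeys the Beer-Lambert law", {
  expect_equal(transmittance(0, 3), 1)
  expect_equal(transmittance(1, 1), 0.1)
  # solve 10^(-x) = 0.5: x = log10(2) = 0.30103
  expect_equal(transmittance(0.30103, 1), 0.5, tolerance = 1e-5)
  cs <- seq(0, 5, by = 0.1)
  tr <- transmittance(cs, 1.7)
  expect_true(all(tr > 0 & tr <= 1))
  expect_true(all(diff(tr) < 0))
  expect_error(transmittance(-1, 1), "concentration")
  expect_error(transmittance(1, -1), "optical_depth_coeff")
})

test_that("rendered frames realise backlight x transmittance inside the heart", {
  sc <- small_scene(noise = 0, I0 = 250)
  mask_px <- c(sc$heart_center[2], sc$heart_center[1])  # centre pixel row/col
  f0 <- render_frame(sc, concentration = 0, optical_depth_coeff = 2)
  expect_equal(f0$pixels[mask_px[1], mask_px[2]], 250L)
  # one absorbance unit: 250 * 0.1 = 25
  f1 <- render_frame(sc, concentration = 1, optical_depth_coeff = 1)
  expect_equal(f1$pixels[mask_px[1], mask_px[2]], 25L)
  expect_true(all(f1$pixels >= 0 & f1$pixels <= 255))
  expect_identical(dim(f1$pixels), c(sc$height_px, sc$width_px))
  # noiseless rendering is deterministic
  expect_identical(render_frame(sc, 0.4, 2)$pixels,
                   render_frame(sc, 0.4, 2)$pixels)
})

test_that("noise-free runs match the Gompertz closed form within rounding", {
  sc <- small_scene(noise = 0)
  m <- dilution_model(40, 50, 1, 2.5)
  run <- simulate_discoloration_run(sc, m, frame_interval_min = 5,
                                    max_frames = 40)
  region <- heart_roi(sc)
  got <- vapply(run$frames, function(f) mean_intensity(f, region), numeric(1))
  want <- sc$backlight_intensity *
    transmittance(dye_concentration(m, run$times_min), m$optical_depth_coeff)
  expect_lt(max(abs(got - want)), 0.5)
  expect_equal(run$ground_truth$true_mean, want, tolerance = 1e-12)
})

test_that("seeded runs are bit-identical and near-zero flow is near-constant", {
  sc <- small_scene(noise = 2, seed = 42)
  m <- dilution_model(40, 50, 1, 2.5)
  r1 <- simulate_discoloration_run(sc, m, 5, 12)
  r2 <- simulate_discoloration_run(sc, m, 5, 12)
  expect_identical(lapply(r1$frames, `[[`, "pixels"),
                   lapply(r2$frames, `[[`, "pixels"))
  # vanishing flow: concentration (and the noise-free trace) barely moves
  slow <- dilution_model(1e6, 1e-6, 1, 2.5)
  run <- simulate_discoloration_run(small_scene(noise = 0), slow, 5, 12)
  expect_lt(diff(range(run$ground_truth$true_mean)), 1e-6)
  expect_warning(simulate_discoloration_run(sc, m, 5, 5), "window")
})

test_that("release kinetics saturate at the plateau", {
  rm_ <- release_model(118, 150, analyte_label = "dna")
  expect_equal(release_concentration(rm_, 0), 0)
  # at t = tau: (1 - exp(-1)) of the plateau
  expect_equal(release_concentration(rm_, 150), 118 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(release_concentration(rm_, 1e5), 118, tolerance = 1e-6)
  expect_error(release_concentration(rm_, -5), "t_min")
  expect_error(release_model(-1, 10), "plateau")
  expect_error(release_model(10, 10, noise_sd = -1), "noise_sd")
})

test_that("sampling hits the 30-min grid, truncates at zero and reproduces", {
  rm0 <- release_model(100, 120, noise_sd = 0, analyte_label = "dna")
  s <- simulate_sampling(rm0, interval_min = 30, duration_min = 600)
  expect_equal(nrow(s), 21L)               # t = 0, 30, ..., 600
  expect_equal(s$time_min, seq(0, 600, by = 30))
  expect_equal(s$value, release_concentration(rm0, s$time_min))
  rmn <- release_model(100, 120, noise_sd = 50, analyte_label = "dna")
  s1 <- simulate_sampling(rmn, 30, 600, seed = 9)
  s2 <- simulate_sampling(rmn, 30, 600, seed = 9)
  expect_identical(s1$value, s2$value)
  expect_true(all(s1$value >= 0))          # truncated-at-zero noise
  expect_false(identical(s1$value, simulate_sampling(rmn, 30, 600, seed = 10)$value))
})

test_that("scene validation rejects out-of-frame hearts and bad intensities", {
  expect_error(phantom_scene(64, 48, heart_center = c(5, 24),
                             heart_semiaxes = c(20, 10)), "within the frame")
  expect_error(phantom_scene(64, 48, backlight_intensity = 300), "0, 255")
  expect_error(dilution_model(0, 50, 1, 1), "reservoir")
  expect_error(dilution_model(50, 50, 1, -1), "optical_depth")
})
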