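series_of <- function(values, dt = 30, analyte = "dna") {
  concentration_series((seq_along(values) - 1) * dt, values, analyte, "ng/uL")
}

test_that("successive differences are absolute adjacent gaps", {
  expect_equal(successive_differences(series_of(rep(5, 6))), rep(0, 5))
  expect_equal(successive_differences(series_of(c(1, 3, 6))), c(2, 3))
  expect_equal(successive_differences(series_of(c(10, 5, 2.5, 1.25))),
               c(5, 2.5, 1.25))
  expect_error(successive_differences(series_of(7)), "2 samples")
})

test_that("plateau detection finds the printed hand-worked endpoint", {
  # diffs 40,30,18,2,0,0,0; range 90 -> eps_abs 1.8; run of 3 starts at d5
  s <- series_of(c(100, 60, 30, 12, 10, 10, 10, 10))
  r <- detect_endpoint(s, endpoint_criteria(0.02, 3))
  expect_equal(r$endpoint_time_min, 150)
  expect_equal(r$epsilon_abs, 1.8)
  expect_equal(r$diffs, c(40, 30, 18, 2, 0, 0, 0))
  # constant series: every diff qualifies; plateau entered at the 2nd sample
  flat <- detect_endpoint(series_of(rep(8, 6)), endpoint_criteria(0.02, 3))
  expect_equal(flat$endpoint_time_min, 30)
  expect_true(flat$flat_series)
  # steady ramp never settles
  ramp <- detect_endpoint(series_of(seq(0, 700, by = 100)),
                          endpoint_criteria(0.02, 3))
  expect_true(is.na(ramp$endpoint_time_min))
})

test_that("detection is scale invariant and time-shift equivariant", {
  set.seed(41)
  base <- cumsum(c(50, -rexp(14, rate = 0.2)))
  base <- pmax(base, 0.5)
  s <- series_of(base)
  e0 <- detect_endpoint(s)$endpoint_time_min
  for (c_mult in c(0.01, 3, 1000)) {
    sc <- series_of(base * c_mult)
    expect_identical(detect_endpoint(sc)$endpoint_time_min, e0)
  }
  shifted <- concentration_series(s$time_min + 120, s$value, "dna", "ng/uL")
  e_sh <- detect_endpoint(shifted)$endpoint_time_min
  if (!is.na(e0)) expect_equal(e_sh, e0 + 120)
})

test_that("detected endpoint is nondecreasing in the release time constant", {
  taus <- seq(40, 220, by = 18)   # 11 values
  eps <- vapply(taus, function(tau) {
    m <- release_model(100, tau, analyte_label = "dna")
    predict_release_endpoint(m, 30, 900)
  }, numeric(1))
  expect_true(all(!is.na(eps)))
  expect_true(all(diff(eps) >= 0))
})

test_that("percent reduction reproduces the benchmark figures exactly", {
  expect_equal(percent_reduction(600, 420), 30)
  expect_equal(percent_reduction(630, 450), 100 * 180 / 630, tolerance = 1e-12)
  expect_equal(round(percent_reduction(630, 450)), 29)
  expect_equal(percent_reduction(500, 500), 0)
  # scale invariance: same ratio, same reduction
  expect_equal(percent_reduction(7 * 600, 7 * 420), percent_reduction(600, 420))
  expect_error(percent_reduction(0, 10), "t_control")
})

test_that("lot comparison assembles endpoints and fails loudly without a plateau", {
  s <- series_of(c(100, 60, 30, 12, 10, 10, 10, 10))
  same <- compare_lots(s, s)
  expect_equal(same$percent_reduction, 0)
  ramp <- series_of(seq(0, 700, by = 100))
  expect_error(compare_lots(s, ramp), "treatment")
  expect_error(compare_lots(ramp, s), "control")
})

test_that("series constructor enforces its invariants", {
  expect_error(concentration_series(c(0, 30), c(1, 2, 3), "dna"), "equal length")
  expect_error(concentration_series(c(0, 0), c(1, 2), "dna"), "increasing")
  expect_error(concentration_series(c(0, 30), c(1, -2), "dna"), ">= 0")
  expect_error(endpoint_criteria(diff_epsilon = 1.5), "diff_epsilon")
  expect_error(endpoint_criteria(run_length_m = 0), "run_length_m")
})
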