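test_that("dilution calibration hits the requested stop time on the oracle", {
  rule <- stopping_rule()
  for (target in c(200, 340)) {
    m <- calibrate_dilution(target, frame_interval_min = 5, rule = rule)
    expect_equal(predict_stop_time(m, 250, rule, 5, 200), target)
  }
})

test_that("release calibration hits the requested endpoint and sits mid-band", {
  m <- calibrate_release(450, plateau_concentration = 79, duration_min = 720)
  expect_equal(predict_release_endpoint(m, 30, 720), 450)
  # one sampling step in either direction of tau moves off the band edges
  edge_lo <- release_model(79, m$time_constant_min * 0.9, analyte_label = "dna")
  edge_hi <- release_model(79, m$time_constant_min * 1.1, analyte_label = "dna")
  expect_lte(predict_release_endpoint(edge_lo, 30, 720), 450)
  expect_gte(predict_release_endpoint(edge_hi, 30, 720), 450)
})

test_that("calibration refuses targets beyond the plateau-collapse regime", {
  # with only 3% allowed variation, a run this long cannot be reached:
  # the initial dark plateau trips the rule first
  expect_error(calibrate_dilution(5000, frame_interval_min = 5,
                                  optical_depth_coeff = 0.5),
               "unreachable|bracket|failed")
})
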