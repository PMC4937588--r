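test_that("waveform parameter invariants are enforced", {
  expect_s3_class(waveform_params(), "waveform_params")
  expect_equal(waveform_params(heart_rate = 75)$cycle_ms, 800)
  expect_error(waveform_params(heart_rate = 0), class = "pwvttf_error_parameter")
  expect_error(waveform_params(upslope_ms = 300, ejection_ms = 300),
               class = "pwvttf_error_parameter")
  expect_error(waveform_params(foot_time_ms = 800, ejection_ms = 300),
               class = "pwvttf_error_parameter")
  expect_error(waveform_params(peak_flow_ml_s = 5, diastolic_ml_s = 10),
               class = "pwvttf_error_parameter")
  expect_error(generate_waveform(waveform_params(), 3),
               class = "pwvttf_error_input")
})

test_that("generated waveform peaks at foot + upslope with the requested amplitude", {
  fc <- generate_waveform(default_params(), 40)
  spacing <- 1000 / 40
  i_max <- which.max(fc$flow_ml_s)
  expect_lte(abs(fc$time_ms[i_max] - 170), spacing)
  expect_lte(max(fc$flow_ml_s), 400)
  expect_gte(max(fc$flow_ml_s), 0.99 * 400)
  # exact at the peak when it falls on a sample
  fc2 <- generate_waveform(waveform_params(foot_time_ms = 75,
                                           upslope_ms = 100,
                                           ejection_ms = 300), 40)
  expect_equal(max(fc2$flow_ml_s), 400)
  expect_equal(fc2$time_ms[which.max(fc2$flow_ml_s)], 175)
})

test_that("near-degenerate amplitude gives a near-flat curve", {
  eps <- 1e-9
  fc <- generate_waveform(waveform_params(peak_flow_ml_s = 10 + eps,
                                          diastolic_ml_s = 10), 64)
  expect_lte(max(fc$flow_ml_s) - min(fc$flow_ml_s), eps)
})

test_that("cycle integral matches the closed-form baseline + pulse area", {
  p <- waveform_params(diastolic_ml_s = 12)
  closed_form <- 12 * p$cycle_ms +
    (p$peak_flow_ml_s - 12) * p$ejection_ms / 2
  quad <- stats::integrate(function(t) waveform_flow(p, t), 0, p$cycle_ms,
                           subdivisions = 2000L, rel.tol = 1e-10)
  expect_lt(abs(quad$value - closed_form) / closed_form, 1e-6)
  fc <- generate_waveform(p, 4000)
  riemann <- sum(fc$flow_ml_s) * p$cycle_ms / 4000
  expect_lt(abs(riemann - closed_form) / closed_form, 0.005)
})

test_that("waveform is C1-smooth: derivative continuous at segment joins", {
  p <- default_params()
  h <- 1e-5
  joins <- c(p$foot_time_ms,
             p$foot_time_ms + p$upslope_ms,
             p$foot_time_ms + p$ejection_ms)
  for (tj in joins) {
    left <- (waveform_flow(p, tj) - waveform_flow(p, tj - h)) / h
    right <- (waveform_flow(p, tj + h) - waveform_flow(p, tj)) / h
    expect_lt(abs(left - right), 1e-3)
  }
  # steepest point lies on the upslope, nowhere else
  t <- seq(0, p$cycle_ms - 0.01, by = 0.01)
  deriv <- diff(waveform_flow(p, t)) / 0.01
  t_steep <- t[which.max(deriv)]
  expect_gte(t_steep, p$foot_time_ms)
  expect_lte(t_steep, p$foot_time_ms + p$upslope_ms)
})

test_that("noise is seed-reproducible and off by default", {
  p_seeded <- waveform_params(noise_sd_ml_s = 5, seed = 11L)
  expect_identical(generate_waveform(p_seeded, 40)$flow_ml_s,
                   generate_waveform(p_seeded, 40)$flow_ml_s)
  noiseless <- waveform_params()
  expect_identical(generate_waveform(noiseless, 40)$flow_ml_s,
                   waveform_flow(noiseless, (0:39) * 25))
})

test_that("phantom pair shift follows delta_t = distance / PWV", {
  p <- default_params()
  expect_equal(make_phantom_pair(p, 2, 250, 40)$shift_ms, 125)
  expect_equal(make_phantom_pair(p, 20, 250, 40)$shift_ms, 12.5)
  pair0 <- make_phantom_pair(p, Inf, 250, 40)
  expect_equal(pair0$shift_ms, 0)
  expect_identical(pair0$proximal$flow_ml_s, pair0$distal$flow_ml_s)
  expect_error(make_phantom_pair(p, -1, 250, 40), class = "pwvttf_error_parameter")
  expect_error(make_phantom_pair(p, 6, -10, 40), class = "pwvttf_error_parameter")
  expect_error(make_phantom_pair(p, 0.2, 250, 40), # shift 1250 >= cycle
               class = "pwvttf_error_parameter")
})

test_that("dense phantom pair feet differ by the injected shift", {
  p <- default_params()
  for (pwv in c(4, 9)) {
    pair <- make_phantom_pair(p, pwv, 250, 10000)
    dt <- transit_time(detect_foot(pair$proximal), detect_foot(pair$distal))
    expect_lt(abs(dt - pair$shift_ms), 0.1) # one dense-grid step
  }
})
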