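test_that("ttf_config validates its parameters", {
  expect_s3_class(ttf_config(), "ttf_config")
  expect_error(ttf_config(upslope_band = c(0.8, 0.2)),
               class = "pwvttf_error_parameter")
  expect_error(ttf_config(upslope_band = c(0, 0.8)),
               class = "pwvttf_error_parameter")
  expect_error(ttf_config(min_upslope_points = 1),
               class = "pwvttf_error_parameter")
  expect_error(ttf_config(baseline_window_frac = 0),
               class = "pwvttf_error_parameter")
})

test_that("tangent intersection is exact for a piecewise-linear pulse", {
  fc <- triangular_curve(n = 100, onset = 100)
  # on the raw samples the tangents are exact lines
  raw <- detect_foot(fc, smoothing = smoothing_spec(sigma_ms = 0),
                     config = ttf_config(interp = "none"))
  expect_equal(raw$foot_time_ms, 100, tolerance = 1e-9)
  expect_gt(raw$upslope$slope, 0)
  expect_equal(raw$upslope$r_squared, 1, tolerance = 1e-12)
  expect_equal(raw$baseline$intercept, 0, tolerance = 1e-9)
  # default dense pipeline stays within half a sample spacing
  dflt <- detect_foot(fc)
  expect_lt(abs(dflt$foot_time_ms - 100), (1000 / 100) / 2)
})

test_that("foot detection is equivariant under circular time shifts", {
  fc <- triangular_curve(n = 100, onset = 100)
  f0 <- detect_foot(fc)$foot_time_ms
  for (k in c(10, 55, 90)) {
    fs <- detect_foot(shift_curve(fc, k))$foot_time_ms
    expect_lt(abs((fs - f0) %% 1000 - (k * 10) %% 1000), 0.01)
  }
})

test_that("foot of the smooth synthetic waveform sits on the early upslope", {
  p <- default_params()
  foot <- detect_foot(generate_waveform(p, 10000))$foot_time_ms
  # the intersecting-tangent foot lies after the onset, well before the peak
  expect_gte(foot, p$foot_time_ms)
  expect_lte(foot, p$foot_time_ms + 0.25 * p$upslope_ms)
  # and is a pure translation of the waveform timing
  p2 <- waveform_params(foot_time_ms = 180)
  foot2 <- detect_foot(generate_waveform(p2, 10000))$foot_time_ms
  expect_equal(foot2 - foot, 100, tolerance = 0.1)
})

test_that("curves without an upstroke are rejected", {
  flat <- flow_curve((0:39) * 25, rep(3, 40), 1000)
  expect_error(detect_foot(flat), class = "pwvttf_error_no_upstroke")
  # excursion below the configurable noise floor counts as flat
  ripple <- flow_curve((0:39) * 25, 3 + 1e-8 * sin((0:39) / 6), 1000)
  expect_error(detect_foot(ripple), class = "pwvttf_error_no_upstroke")
  # a periodic falling ramp is a sawtooth: its only upstroke is the wrap jump
  falling <- flow_curve((0:39) * 25, seq(100, 2.5, length.out = 40), 1000)
  wrap_foot <- detect_foot(falling, smoothing = smoothing_spec(sigma_ms = 0),
                           config = ttf_config(interp = "none"))
  expect_gt(wrap_foot$foot_time_ms, 900)
})

test_that("transit time subtracts feet modulo the cycle", {
  expect_equal(transit_time(80, 205, cycle_ms = 1000), 125)
  expect_equal(transit_time(990, 15, cycle_ms = 1000), 25)
  expect_warning(dt <- transit_time(100, 100, cycle_ms = 1000),
                 class = "pwvttf_warning_nonphysiologic")
  expect_equal(dt, 0)
  expect_warning(transit_time(205, 80, cycle_ms = 1000),
                 class = "pwvttf_warning_nonphysiologic")
  f1 <- detect_foot(generate_waveform(default_params(), 2000))
  f2 <- detect_foot(generate_waveform(waveform_params(heart_rate = 75), 2000))
  expect_error(transit_time(f1, f2), class = "pwvttf_error_input")
})

test_that("PWV arithmetic and guards follow distance / transit time", {
  expect_equal(compute_pwv(250, 50), 5)
  expect_equal(compute_pwv(250, 55.6), 4.496, tolerance = 1e-3)
  expect_error(compute_pwv(250, 0), class = "pwvttf_error_nonphysiologic")
  expect_error(compute_pwv(250, -5), class = "pwvttf_error_nonphysiologic")
  expect_error(compute_pwv(-1, 50), class = "pwvttf_error_parameter")
  # homogeneity: doubling distance doubles PWV exactly
  expect_identical(compute_pwv(500, 37.3), 2 * compute_pwv(250, 37.3))
})

test_that("automatic baseline offset is the late-diastolic mean", {
  const <- flow_curve((0:39) * 25, rep(17, 40), 1000)
  expect_equal(auto_baseline_offset(const), 17)
  fc <- generate_waveform(default_params(), 40)
  expect_lt(abs(auto_baseline_offset(fc)), 1e-9)
  raised <- flow_curve(fc$time_ms, fc$flow_ml_s + 17, 1000)
  expect_equal(auto_baseline_offset(raised), 17, tolerance = 1e-9)
})

test_that("baseline correction is idempotent and honours the manual path", {
  fc <- generate_waveform(default_params(), 40)
  raised <- flow_curve(fc$time_ms, fc$flow_ml_s + 23, 1000)
  corrected <- apply_baseline_correction(raised)        # automatic
  expect_lt(abs(auto_baseline_offset(corrected)), 1e-9)
  expect_equal(corrected$flow_ml_s, fc$flow_ml_s, tolerance = 1e-9)
  expect_identical(apply_baseline_correction(raised, 0)$flow_ml_s,
                   raised$flow_ml_s)
  # genuine diastolic (regurgitant) flow biases the automatic estimate:
  # the diastolic level is real, not an eddy-current offset
  regurg <- generate_waveform(waveform_params(diastolic_ml_s = -30), 40)
  expect_equal(auto_baseline_offset(regurg), -30, tolerance = 1e-9)
  manual <- apply_baseline_correction(regurg, 0)        # manual: leave it
  expect_identical(manual$flow_ml_s, regurg$flow_ml_s)
})

test_that("dense noiseless phantoms are recovered within 1 %", {
  pair <- make_phantom_pair(default_params(), 6, 250, 10000)
  res <- measure_pwv(pair$proximal, pair$distal, 250)
  expect_lt(abs(res$pwv_m_s - 6) / 6, 0.01)
  expect_equal(res$pwv_m_s, res$distance_mm / res$delta_t_ms,
               tolerance = 1e-12)
  g <- glance(res)
  expect_equal(g$pwv_m_s, res$pwv_m_s)
  expect_equal(nrow(tidy(res)), 2L)
})

test_that("a 35-frame phantom stays within the plateau tolerance", {
  pair <- make_phantom_pair(default_params(), 8, 250, 35)
  res <- measure_pwv(pair$proximal, pair$distal, 250)
  expect_lt(abs(res$pwv_m_s - 8) / 8, 0.06)
})

test_that("zero shift raises a non-physiologic transit-time error", {
  pair <- make_phantom_pair(default_params(), Inf, 250, 2000)
  err <- expect_error(measure_pwv(pair$proximal, pair$distal, 250),
                      class = "pwvttf_error_nonphysiologic")
  expect_true(err$delta_t_ms <= 0)
})

test_that("measurement is invariant to flow scaling and common time shifts", {
  pair <- make_phantom_pair(default_params(), 7, 250, 40)
  base <- measure_pwv(pair$proximal, pair$distal, 250)
  scale <- function(curve, k) {
    flow_curve(curve$time_ms, k * curve$flow_ml_s, cycle_ms(curve))
  }
  scaled <- measure_pwv(scale(pair$proximal, 3.7), scale(pair$distal, 3.7), 250)
  expect_equal(scaled$pwv_m_s, base$pwv_m_s, tolerance = 1e-9)
  expect_equal(scaled$proximal_foot$foot_time_ms,
               base$proximal_foot$foot_time_ms, tolerance = 1e-9)
  shifted <- measure_pwv(shift_curve(pair$proximal, 8),
                         shift_curve(pair$distal, 8), 250)
  expect_lt(abs(shifted$delta_t_ms - base$delta_t_ms), 0.01)
  doubled <- measure_pwv(pair$proximal, pair$distal, 500)
  expect_equal(doubled$pwv_m_s, 2 * base$pwv_m_s, tolerance = 1e-12)
})
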