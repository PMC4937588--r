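test_that("smoothing spec resolves sigma against the acquired frame interval", {
  fc40 <- generate_waveform(default_params(), 40)
  expect_equal(resolve_sigma_ms(smoothing_spec(sigma_frac = 0.025), fc40), 0.625)
  expect_equal(resolve_sigma_ms(smoothing_spec(sigma_ms = 0.62), fc40), 0.62)
  expect_error(smoothing_spec(), class = "pwvttf_error_parameter")
  expect_error(smoothing_spec(sigma_ms = 1, sigma_frac = 0.1),
               class = "pwvttf_error_parameter")
  expect_error(smoothing_spec(sigma_ms = -1), class = "pwvttf_error_parameter")
})

test_that("cubic upsampling preserves nodes and yields the requested grid", {
  fc <- generate_waveform(default_params(), 40)
  up <- upsample_cubic(fc, 10000)
  expect_equal(nrow(up), 10000)
  expect_equal(diff(up$time_ms)[1], 0.1)          # 0.1 ms grid
  # interpolant passes through all original samples (they lie on the new grid)
  at_nodes <- up$flow_ml_s[match(fc$time_ms, up$time_ms)]
  expect_equal(at_nodes, fc$flow_ml_s, tolerance = 1e-12)
  expect_error(upsample_cubic(fc, 40), class = "pwvttf_error_input")
})

test_that("non-periodic cubic upsampling reproduces a global cubic exactly", {
  t <- (0:19) * 50
  poly <- function(x) 2 + 0.03 * x - 4e-5 * x^2 + 1.5e-8 * x^3
  fc <- flow_curve(t, poly(t), 1000)
  up <- upsample_cubic(fc, 500, method = "fmm")
  interior <- up$time_ms <= max(t)
  expect_equal(up$flow_ml_s[interior], poly(up$time_ms[interior]),
               tolerance = 1e-9)
})

test_that("anti-aliased downsampling preserves DC and removes above-Nyquist content", {
  cyc <- 1000
  t <- (0:1999) * cyc / 2000
  const <- flow_curve(t, rep(42, 2000), cyc)
  for (filt in c("windowed_sinc", "ideal")) {
    dn <- downsample_antialiased(const, 25, filter = filt)
    expect_equal(dn$flow_ml_s, rep(42, 25), tolerance = 1e-9)
  }
  # sinusoid well below target Nyquist (harmonic 4 of 10) survives within 1 %
  low <- flow_curve(t, 100 + 50 * sin(2 * pi * 4 * t / cyc), cyc)
  expect_lt(abs(harmonic_amplitude(downsample_antialiased(low, 20), 4) - 50) / 50,
            0.01)
  # sinusoid above target Nyquist (harmonic 14) is attenuated by >= 90 %
  hi <- flow_curve(t, 100 + 50 * sin(2 * pi * 14 * t / cyc), cyc)
  dn <- downsample_antialiased(hi, 20)
  expect_lt(max(abs(dn$flow_ml_s - 100)), 0.1 * 50)
  expect_error(downsample_antialiased(low, 3000), class = "pwvttf_error_input")
})

test_that("frame spacing of the default grid spans 50 to 25 ms", {
  dense <- generate_waveform(default_params(), 10000)
  spacings <- vapply(c(20L, 30L, 40L), function(n) {
    diff(downsample_antialiased(dense, n)$time_ms)[1]
  }, numeric(1))
  expect_equal(spacings, c(50, 1000 / 30, 25))
})

test_that("all resampling operations conserve the signal mean", {
  fc <- generate_waveform(default_params(), 40)
  mu <- mean(fc$flow_ml_s)
  expect_equal(mean(upsample_cubic(fc, 2000)$flow_ml_s), mu, tolerance = 1e-6)
  dense <- generate_waveform(default_params(), 2000)
  expect_equal(mean(downsample_antialiased(dense, 40)$flow_ml_s),
               mean(dense$flow_ml_s), tolerance = 1e-6)
  expect_equal(mean(gaussian_smooth(fc, smoothing_spec(sigma_ms = 10))$flow_ml_s),
               mu, tolerance = 1e-6)
})

test_that("upsample then downsample returns a band-limited curve", {
  cyc <- 1000
  t <- (0:99) * 10
  fc <- flow_curve(t, 100 + 40 * sin(2 * pi * 3 * t / cyc) +
                     20 * cos(2 * pi * 6 * t / cyc), cyc)
  rt <- downsample_antialiased(upsample_cubic(fc, 5000), 100)
  rms <- sqrt(mean((rt$flow_ml_s - fc$flow_ml_s)^2))
  expect_lt(rms / max(abs(fc$flow_ml_s)), 0.01)
})

test_that("filtering and smoothing are zero-phase: symmetric pulse centroid is fixed", {
  cyc <- 1000
  t <- (0:1999) * 0.5
  pulse <- exp(-((t - 400)^2) / (2 * 30^2))         # symmetric around 400 ms
  fc <- flow_curve(t, pulse, cyc)
  centroid <- function(curve) {
    w <- curve$flow_ml_s - min(curve$flow_ml_s)
    sum(curve$time_ms * w) / sum(w)
  }
  c0 <- centroid(fc)
  expect_lt(abs(centroid(downsample_antialiased(fc, 50)) - c0), cyc / 2000 + 1)
  expect_lt(abs(centroid(gaussian_smooth(fc, smoothing_spec(sigma_ms = 8))) - c0),
            cyc / 2000)
})

test_that("gaussian smoothing identity cases hold", {
  fc <- generate_waveform(default_params(), 40)
  expect_equal(gaussian_smooth(fc, smoothing_spec(sigma_ms = 0))$flow_ml_s,
               fc$flow_ml_s)
  const <- flow_curve((0:39) * 25, rep(7, 40), 1000)
  expect_equal(gaussian_smooth(const, smoothing_spec(sigma_ms = 40))$flow_ml_s,
               rep(7, 40), tolerance = 1e-12)
})

test_that("halving the smoothing sigma barely moves a clean phantom PWV", {
  pair <- make_phantom_pair(default_params(), 6, 250, 40)
  pwv_at <- function(sig) {
    measure_pwv(pair$proximal, pair$distal, 250,
                smoothing = smoothing_spec(sigma_ms = sig))$pwv_m_s
  }
  delta <- pwv_at(0.34) - pwv_at(0.68)
  expect_lt(abs(delta), 0.05)
})
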