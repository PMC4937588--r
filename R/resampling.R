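#' Smoothing specification
#'
#' Width of the Gaussian kernel applied to flow curves before tangent
#' fitting. The width can be given in milliseconds (`sigma_ms`) or as a
#' fraction of the acquired frame interval (`sigma_frac`); exactly one of
#' the two must be supplied. The fractional form follows clinical practice
#' of scaling the smoothing with temporal resolution: at 60 bpm and 40
#' frames (25 ms spacing) the default `sigma_frac = 0.025` resolves to
#' 0.625 ms.
#'
#' @param sigma_ms Gaussian standard deviation in ms (>= 0).
#' @param sigma_frac Gaussian standard deviation as a fraction of the frame
#'   interval of the curve it is applied to.
#' @return A `smoothing_spec` list.
#' @examples
#' resolve_sigma_ms(smoothing_spec(sigma_frac = 0.025),
#'                  generate_waveform(waveform_params(), 40))
#' @export
smoothing_spec <- function(sigma_ms = NULL, sigma_frac = NULL) {
  if (is.null(sigma_ms) == is.null(sigma_frac)) {
    stop_parameter("give exactly one of `sigma_ms` or `sigma_frac`")
  }
  if (!is.null(sigma_ms)) check_number(sigma_ms, "sigma_ms", lower = 0)
  if (!is.null(sigma_frac)) check_number(sigma_frac, "sigma_frac", lower = 0)
  structure(list(sigma_ms = sigma_ms, sigma_frac = sigma_frac),
            class = "smoothing_spec")
}

#' @rdname smoothing_spec
#' @param spec A `smoothing_spec`.
#' @param curve The [flow_curve()] the spec refers to (used for its frame
#'   interval when `sigma_frac` is given).
#' @export
resolve_sigma_ms <- function(spec, curve) {
  stopifnot(inherits(spec, "smoothing_spec"))
  if (!is.null(spec$sigma_ms)) return(spec$sigma_ms)
  spec$sigma_frac * frame_interval_ms(curve)
}

#' Dense cubic upsampling of a flow curve
#'
#' Resamples a flow curve to a finer uniform grid with cubic-spline
#' interpolation. The default periodic end condition treats the cycle as one
#' period of a periodic signal (the natural model for retrospectively gated
#' data); `method = "fmm"` or `"natural"` give the classical non-periodic
#' end conditions. The interpolant passes through every original sample.
#'
#' @param curve A uniformly sampled [flow_curve()].
#' @param n_target Output frame count; must exceed the input frame count.
#' @param method Spline end condition, one of `"periodic"`, `"fmm"`,
#'   `"natural"`.
#' @return A [flow_curve()] with `n_target` uniform samples.
#' @examples
#' up <- upsample_cubic(generate_waveform(waveform_params(), 40), 10000)
#' diff(up$time_ms)[1]  # 0.1 ms
#' @export
upsample_cubic <- function(curve, n_target,
                           method = c("periodic", "fmm", "natural")) {
  check_uniform(curve, "upsample_cubic()")
  method <- match.arg(method)
  n_target <- check_count(n_target, "n_target", lower = 2L)
  if (n_target <= nrow(curve)) {
    stop_input("`n_target` must exceed the input frame count")
  }
  cyc <- cycle_ms(curve)
  t_out <- uniform_times(n_target, cyc)
  if (method == "periodic") {
    # close the period with the wrap-around node so splinefun sees y[1] == y[n+1]
    sf <- splinefun(c(curve$time_ms, curve$time_ms[1L] + cyc),
                    c(curve$flow_ml_s, curve$flow_ml_s[1L]),
                    method = "periodic")
    f_out <- sf((t_out - curve$time_ms[1L]) %% cyc + curve$time_ms[1L])
  } else {
    sf <- splinefun(curve$time_ms, curve$flow_ml_s, method = method)
    f_out <- sf(t_out)
  }
  flow_curve(t_out, f_out, cyc)
}

# exact Fourier (band-limited) resampling of a uniform periodic signal;
# optional per-harmonic weights w (length = length(y) spectrum) applied first
fourier_resample <- function(y, n_out, weights = NULL) {
  n_in <- length(y)
  spec <- fft(y) / n_in
  if (!is.null(weights)) spec <- spec * weights
  out <- complex(real = numeric(n_out), imaginary = numeric(n_out))
  h <- min((n_in - 1L) %/% 2L, (n_out - 1L) %/% 2L)
  out[1L] <- spec[1L]
  if (h >= 1L) {
    k <- seq_len(h)
    out[k + 1L] <- spec[k + 1L]
    out[n_out + 1L - k] <- spec[n_in + 1L - k]
  }
  if (n_out < n_in && n_out %% 2L == 0L) {
    # both +/- n_out/2 harmonics of the input alias onto the output Nyquist bin
    out[n_out / 2L + 1L] <- spec[n_out / 2L + 1L] + spec[n_in + 1L - n_out / 2L]
  } else if (n_out > n_in && n_in %% 2L == 0L) {
    # split the input Nyquist energy symmetrically
    out[n_in / 2L + 1L] <- spec[n_in / 2L + 1L] / 2
    out[n_out + 1L - n_in / 2L] <- spec[n_in / 2L + 1L] / 2
  }
  Re(fft(out, inverse = TRUE))
}

# zero-phase frequency response of a Hamming-windowed sinc low-pass defined on
# a length-n periodic grid; cutoff in harmonics (cycles per cardiac cycle)
windowed_sinc_response <- function(n, cutoff, taps_per_step) {
  decim <- n / (2 * cutoff)             # dense samples per target frame
  half <- max(3L, ceiling(taps_per_step * decim / 2))
  m <- (-half):half
  h <- ifelse(m == 0L, 2 * cutoff / n, sin(2 * pi * cutoff * m / n) / (pi * m))
  w <- 0.54 + 0.46 * cos(pi * m / half) # Hamming window
  h <- h * w
  h <- h / sum(h)                       # exact unit DC gain
  kern <- numeric(n)
  kern[1L] <- h[half + 1L]
  idx <- seq_len(half)
  kern[1L + idx] <- h[half + 1L + idx]
  kern[n + 1L - idx] <- h[half + 1L - idx]
  Re(fft(kern))                         # symmetric kernel -> real, zero phase
}

#' Anti-aliased downsampling of a flow curve
#'
#' Reduces a uniformly sampled flow curve to `n_frames` samples per cycle
#' after zero-phase low-pass filtering at the target Nyquist frequency
#' (`n_frames / (2 * cycle)`), emulating the smoothing an acquisition at that
#' temporal resolution would impose. `filter = "windowed_sinc"` (default)
#' applies a zero-phase Hamming-windowed-sinc response; `"ideal"` applies a
#' brick-wall cutoff. Sampling onto the coarse grid is exact (spectral), so
#' the filter introduces no phase delay — any phase delay would bias the
#' transit time. A constant curve maps to the same constant.
#'
#' @param curve A uniformly sampled [flow_curve()].
#' @param n_frames Output frame count (>= 4, below the input frame count).
#' @param filter `"windowed_sinc"` or `"ideal"`.
#' @param taps_per_step Windowed-sinc kernel length in units of the output
#'   frame interval (ignored for `"ideal"`).
#' @return A [flow_curve()] with `n_frames` uniform samples.
#' @export
downsample_antialiased <- function(curve, n_frames,
                                   filter = c("windowed_sinc", "ideal"),
                                   taps_per_step = 6) {
  check_uniform(curve, "downsample_antialiased()")
  n_frames <- check_count(n_frames, "n_frames", lower = 4L)
  n_in <- nrow(curve)
  if (n_frames >= n_in) {
    stop_input("`n_frames` must be below the input frame count")
  }
  filter <- match.arg(filter)
  weights <- if (filter == "windowed_sinc") {
    windowed_sinc_response(n_in, cutoff = n_frames / 2, taps_per_step)
  }
  f_out <- fourier_resample(curve$flow_ml_s, n_frames, weights = weights)
  flow_curve(uniform_times(n_frames, cycle_ms(curve)), f_out, cycle_ms(curve))
}

#' Gaussian smoothing of a flow curve
#'
#' Circular (periodic) convolution with a unit-area Gaussian kernel. With
#' `sigma_ms = 0` the input is returned unchanged; a constant curve is
#' unchanged for any sigma. Used before tangent fitting to stabilise the
#' maximal-upslope regression on noisy curves.
#'
#' @param curve A uniformly sampled [flow_curve()].
#' @param spec A [smoothing_spec()]; `sigma_frac` is resolved against this
#'   curve's frame interval.
#' @return A smoothed [flow_curve()].
#' @export
gaussian_smooth <- function(curve, spec = smoothing_spec(sigma_frac = 0.025)) {
  check_uniform(curve, "gaussian_smooth()")
  sigma <- resolve_sigma_ms(spec, curve)
  flow_curve(curve$time_ms,
             gaussian_smooth_values(curve$flow_ml_s, frame_interval_ms(curve), sigma),
             cycle_ms(curve))
}

gaussian_smooth_values <- function(f, dt_ms, sigma_ms) {
  if (sigma_ms < 0) stop_parameter("`sigma_ms` must be non-negative")
  if (sigma_ms == 0) return(f)
  n <- length(f)
  half <- n %/% 2L
  lag <- c(0:half, -((n - half - 1L):1L)) * dt_ms
  kern <- exp(-lag^2 / (2 * sigma_ms^2))
  kern <- kern / sum(kern)
  Re(fft(fft(f) * fft(kern), inverse = TRUE)) / n
}
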