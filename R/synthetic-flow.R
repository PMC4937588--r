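#' Synthetic aortic waveform parameters
#'
#' Parameter set for the built-in aortic flow-waveform model: a flat diastolic
#' baseline with a single systolic pulse, built from a raised-cosine upslope
#' (onset at `foot_time_ms`, peak at `foot_time_ms + upslope_ms`) and a
#' raised-cosine decay returning to baseline at `foot_time_ms + ejection_ms`.
#' The segments join with matching first derivatives, so the waveform is
#' C1-smooth over the whole (periodic) cycle. Defaults describe a normal
#' resting aortic flow curve at 60 beats per minute.
#'
#' @param heart_rate Beats per minute; the cycle length is `60000 / heart_rate` ms.
#' @param peak_flow_ml_s Peak systolic flow in ml/s.
#' @param foot_time_ms Onset of the systolic upslope in ms after the R-wave.
#' @param upslope_ms Duration of the upslope (foot to peak) in ms.
#' @param ejection_ms Duration of the whole systolic pulse (foot to return to
#'   baseline) in ms; must exceed `upslope_ms`.
#' @param diastolic_ml_s Diastolic baseline flow in ml/s.
#' @param noise_sd_ml_s Standard deviation of optional additive Gaussian
#'   noise in ml/s; 0 (the default) gives a noiseless curve.
#' @param seed Integer seed making the noise reproducible; ignored when
#'   `noise_sd_ml_s = 0`.
#'
#' @return A `waveform_params` list.
#' @examples
#' p <- waveform_params()
#' p$cycle_ms
#' @export
waveform_params <- function(heart_rate = 60,
                            peak_flow_ml_s = 400,
                            foot_time_ms = 80,
                            upslope_ms = 90,
                            ejection_ms = 300,
                            diastolic_ml_s = 0,
                            noise_sd_ml_s = 0,
                            seed = NULL) {
  check_number(heart_rate, "heart_rate", lower = .Machine$double.eps)
  cycle <- 60000 / heart_rate
  check_number(foot_time_ms, "foot_time_ms", lower = 0)
  check_number(upslope_ms, "upslope_ms", lower = .Machine$double.eps)
  check_number(ejection_ms, "ejection_ms", lower = .Machine$double.eps)
  check_number(peak_flow_ml_s, "peak_flow_ml_s")
  check_number(diastolic_ml_s, "diastolic_ml_s")
  check_number(noise_sd_ml_s, "noise_sd_ml_s", lower = 0)
  if (upslope_ms >= ejection_ms) {
    stop_parameter("`upslope_ms` must be smaller than `ejection_ms`")
  }
  if (foot_time_ms + ejection_ms > cycle) {
    stop_parameter(sprintf(
      "systolic pulse (foot %g + ejection %g ms) exceeds the %g ms cycle",
      foot_time_ms, ejection_ms, cycle))
  }
  if (peak_flow_ml_s <= diastolic_ml_s) {
    stop_parameter("`peak_flow_ml_s` must exceed `diastolic_ml_s`")
  }
  if (!is.null(seed)) seed <- check_count(seed, "seed", lower = 0L)
  structure(list(heart_rate = heart_rate,
                 cycle_ms = cycle,
                 peak_flow_ml_s = peak_flow_ml_s,
                 foot_time_ms = foot_time_ms,
                 upslope_ms = upslope_ms,
                 ejection_ms = ejection_ms,
                 diastolic_ml_s = diastolic_ml_s,
                 noise_sd_ml_s = noise_sd_ml_s,
                 seed = seed),
            class = "waveform_params")
}

#' Evaluate the continuous synthetic waveform
#'
#' Evaluates the noiseless waveform model at arbitrary times. The model is
#' periodic, so times outside `[0, cycle_ms)` are wrapped.
#'
#' @param params A [waveform_params()] object.
#' @param t_ms Numeric vector of times in ms.
#' @return Numeric vector of flows in ml/s.
#' @export
waveform_flow <- function(params, t_ms) {
  stopifnot(inherits(params, "waveform_params"))
  tt <- t_ms %% params$cycle_ms
  d <- params$diastolic_ml_s
  amp <- params$peak_flow_ml_s - d
  foot <- params$foot_time_ms
  up <- params$upslope_ms
  ej <- params$ejection_ms
  f <- rep(d, length(tt))
  ris <- tt >= foot & tt < foot + up
  f[ris] <- d + amp * 0.5 * (1 - cos(pi * (tt[ris] - foot) / up))
  dec <- tt >= foot + up & tt < foot + ej
  f[dec] <- d + amp * 0.5 * (1 + cos(pi * (tt[dec] - foot - up) / (ej - up)))
  f
}

#' Generate a sampled synthetic aortic flow curve
#'
#' Samples the continuous waveform model at `n_frames` uniform time points
#' over one cardiac cycle, optionally adding white Gaussian noise.
#'
#' @inheritParams waveform_flow
#' @param n_frames Number of uniformly spaced frames (at least 4).
#' @return A [flow_curve()].
#' @examples
#' generate_waveform(waveform_params(), n_frames = 40)
#' @export
generate_waveform <- function(params, n_frames) {
  stopifnot(inherits(params, "waveform_params"))
  n_frames <- check_count(n_frames, "n_frames", lower = 4L)
  t <- uniform_times(n_frames, params$cycle_ms)
  f <- waveform_flow(params, t)
  if (params$noise_sd_ml_s > 0) {
    f <- f + draw_noise(n_frames, params$noise_sd_ml_s, params$seed)
  }
  flow_curve(t, f, params$cycle_ms)
}

draw_noise <- function(n, sd, seed) {
  if (is.null(seed)) return(rnorm(n, sd = sd))
  withr::with_seed(seed, rnorm(n, sd = sd))
}

#' Build a phantom flow-curve pair with a known pulse wave velocity
#'
#' Constructs the computer-phantom input for the temporal-resolution
#' experiment: a proximal curve from the waveform model, and a distal curve
#' that is the same waveform circularly delayed by
#' `shift_ms = distance_mm / pwv_true` (mm divided by m/s gives ms directly).
#' Both are evaluated analytically on a dense uniform grid of `dense_n`
#' points and, when `n_frames < dense_n`, down-sampled with the anti-aliased
#' resampler to the acquired frame count.
#'
#' @inheritParams generate_waveform
#' @param pwv_true True pulse wave velocity in m/s (`Inf` gives zero shift).
#' @param distance_mm Distance between the two flow planes in mm.
#' @param n_frames Acquired frame count for the output pair.
#' @param dense_n Dense evaluation grid size (default 10000, i.e. 0.1 ms
#'   resolution of a 1000 ms cycle).
#' @param filter Anti-aliasing filter passed to [downsample_antialiased()].
#' @return A `phantom_pair` list with elements `proximal`, `distal`
#'   (flow curves), `shift_ms`, `pwv_true` and `distance_mm`.
#' @examples
#' pair <- make_phantom_pair(waveform_params(), pwv_true = 2,
#'                           distance_mm = 250, n_frames = 40)
#' pair$shift_ms  # 125 ms
#' @export
make_phantom_pair <- function(params, pwv_true, distance_mm, n_frames,
                              dense_n = 10000,
                              filter = c("windowed_sinc", "ideal")) {
  stopifnot(inherits(params, "waveform_params"))
  check_number(pwv_true, "pwv_true", lower = .Machine$double.eps, allow_inf = TRUE)
  check_number(distance_mm, "distance_mm", lower = .Machine$double.eps)
  n_frames <- check_count(n_frames, "n_frames", lower = 4L)
  dense_n <- check_count(dense_n, "dense_n", lower = 4L)
  if (n_frames > dense_n) {
    stop_parameter("`n_frames` cannot exceed `dense_n`")
  }
  filter <- match.arg(filter)
  shift <- if (is.infinite(pwv_true)) 0 else distance_mm / pwv_true
  if (shift >= params$cycle_ms) {
    stop_parameter(sprintf(
      "temporal shift %.1f ms is not below the %g ms cycle; pwv_true too small",
      shift, params$cycle_ms))
  }
  td <- uniform_times(dense_n, params$cycle_ms)
  proximal <- flow_curve(td, waveform_flow(params, td), params$cycle_ms)
  distal <- flow_curve(td, waveform_flow(params, td - shift), params$cycle_ms)
  if (n_frames < dense_n) {
    proximal <- downsample_antialiased(proximal, n_frames, filter = filter)
    distal <- downsample_antialiased(distal, n_frames, filter = filter)
  }
  if (params$noise_sd_ml_s > 0) {
    add_noise <- function(curve, seed) {
      flow_curve(curve$time_ms,
                 curve$flow_ml_s + draw_noise(nrow(curve), params$noise_sd_ml_s, seed),
                 cycle_ms(curve))
    }
    proximal <- add_noise(proximal, params$seed)
    distal <- add_noise(distal, if (is.null(params$seed)) NULL else params$seed + 1L)
  }
  structure(list(proximal = proximal, distal = distal,
                 shift_ms = shift, pwv_true = pwv_true,
                 distance_mm = distance_mm),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf(
    "# Phantom pair: true PWV %g m/s over %g mm -> shift %.3f ms, %d frames\n",
    x$pwv_true, x$distance_mm, x$shift_ms, nrow(x$proximal)))
  invisible(x)
}
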