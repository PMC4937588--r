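#' Configuration of the time-to-foot detector
#'
#' Tuning parameters for [detect_foot()] and [measure_pwv()].
#'
#' Sub-sample foot timing needs a dense reconstruction of the sampled curve:
#' the acquired samples locate the systolic upstroke (maximum circular first
#' difference, earliest sample on ties), the curve is then interpolated onto
#' a dense uniform grid where both tangents are fitted. `interp = "fourier"`
#' (default) uses band-limited interpolation — the exact reconstruction of a
#' uniformly sampled periodic signal; `"cubic"` uses a periodic cubic spline;
#' `"none"` fits on the acquired samples only (no sub-sample refinement
#' beyond the tangent intersection itself).
#'
#' @param upslope_band Fractions of (peak - baseline) delimiting the upslope
#'   regression window; samples on the rising limb whose flow falls inside
#'   the band are used.
#' @param min_upslope_points Minimum number of samples in the upslope fit.
#' @param baseline_window_frac Fraction of the cycle immediately preceding
#'   the maximal-upslope point over which the baseline tangent is estimated.
#' @param baseline_fit_slope If `TRUE`, fit the baseline tangent as a
#'   regression line over the baseline window; the default `FALSE` uses a
#'   horizontal tangent at the window's mean flow.
#' @param max_baseline_slope Near-zero bound (ml/s per ms) a fitted baseline
#'   slope may not exceed in magnitude.
#' @param interp Dense reconstruction used for tangent fitting: `"fourier"`,
#'   `"cubic"` or `"none"`.
#' @param interp_n Dense analysis grid size per cycle (used when the curve
#'   has fewer samples).
#' @param noise_floor_ml_s Minimum peak-to-peak flow excursion below which
#'   the curve is declared to have no upstroke.
#' @return A `ttf_config` list.
#' @export
ttf_config <- function(upslope_band = c(0.2, 0.8),
                       min_upslope_points = 3L,
                       baseline_window_frac = 0.10,
                       baseline_fit_slope = FALSE,
                       max_baseline_slope = 0.5,
                       interp = c("fourier", "cubic", "none"),
                       interp_n = 10000,
                       noise_floor_ml_s = 1e-6) {
  if (length(upslope_band) != 2L || !is.numeric(upslope_band) ||
      upslope_band[1L] <= 0 || upslope_band[2L] >= 1 ||
      upslope_band[1L] >= upslope_band[2L]) {
    stop_parameter("`upslope_band` must be two increasing fractions in (0, 1)")
  }
  min_upslope_points <- check_count(min_upslope_points, "min_upslope_points",
                                    lower = 2L, class = stop_parameter)
  check_number(baseline_window_frac, "baseline_window_frac",
               lower = .Machine$double.eps, upper = 0.5)
  check_number(max_baseline_slope, "max_baseline_slope", lower = 0)
  check_number(noise_floor_ml_s, "noise_floor_ml_s", lower = 0)
  structure(list(upslope_band = as.numeric(upslope_band),
                 min_upslope_points = min_upslope_points,
                 baseline_window_frac = baseline_window_frac,
                 baseline_fit_slope = isTRUE(baseline_fit_slope),
                 max_baseline_slope = max_baseline_slope,
                 interp = match.arg(interp),
                 interp_n = check_count(interp_n, "interp_n", lower = 16L,
                                        class = stop_parameter),
                 noise_floor_ml_s = noise_floor_ml_s),
            class = "ttf_config")
}

new_tangent_fit <- function(slope, intercept, fit_window, r_squared) {
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 fit_window = unname(fit_window), r_squared = unname(r_squared)),
            class = "tangent_fit")
}

#' @export
print.tangent_fit <- function(x, ...) {
  cat(sprintf("# Tangent: slope %.4g ml/s/ms, intercept %.4g ml/s, window [%.1f, %.1f] ms, R^2 %s\n",
              x$slope, x$intercept, x$fit_window[1L], x$fit_window[2L],
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' Locate the systolic foot of a flow curve by intersecting tangents
#'
#' Implements the time-to-foot (TTF) detector: after optional Gaussian
#' smoothing, a regression line is fitted to the maximal systolic upslope
#' and a baseline tangent to the window preceding the upstroke; the foot is
#' the time at which the two lines intersect.
#'
#' The upstroke is anchored at the maximal circular first difference of the
#' acquired samples, refined on the dense reconstruction (see
#' [ttf_config()]); the upslope window is the contiguous rising-limb region
#' whose flow lies within `upslope_band` of the peak-to-baseline excursion.
#' Tangent lines are expressed as `flow = intercept + slope * t` in an
#' unwrapped time frame around the upstroke, so `intercept` is the
#' extrapolated flow at `t = 0` of that frame.
#'
#' @param curve A uniformly sampled [flow_curve()] containing a systolic
#'   upstroke.
#' @param smoothing A [smoothing_spec()]; `sigma_frac` resolves against the
#'   acquired frame interval of `curve`.
#' @param config A [ttf_config()].
#' @return A `foot_result` list: `foot_time_ms`, `upslope` and `baseline`
#'   (`tangent_fit` objects), and `cycle_ms`.
#' @examples
#' fc <- generate_waveform(waveform_params(), 10000)
#' detect_foot(fc)$foot_time_ms
#' @export
detect_foot <- function(curve,
                        smoothing = smoothing_spec(sigma_frac = 0.025),
                        config = ttf_config()) {
  check_uniform(curve, "detect_foot()")
  stopifnot(inherits(config, "ttf_config"))
  f_acq <- curve$flow_ml_s
  n <- length(f_acq)
  cyc <- cycle_ms(curve)
  if (max(f_acq) - min(f_acq) <= config$noise_floor_ml_s) {
    abort("no upstroke detected: flow excursion below the noise floor",
          class = "pwvttf_error_no_upstroke")
  }
  d_acq <- circular_diff(f_acq)
  if (all(d_acq <= 0)) {
    abort("no upstroke detected: no positive-slope region",
          class = "pwvttf_error_no_upstroke")
  }
  sigma <- resolve_sigma_ms(smoothing, curve)

  # dense analysis grid
  if (config$interp == "none" || n >= config$interp_n) {
    td <- curve$time_ms
    g <- gaussian_smooth_values(f_acq, frame_interval_ms(curve), sigma)
  } else {
    m <- config$interp_n
    td <- uniform_times(m, cyc)
    g <- switch(config$interp,
                fourier = fourier_resample(f_acq, m),
                cubic = upsample_cubic(curve, m)$flow_ml_s)
    # acquired grid may be offset; fourier/cubic grids start at t = 0
    td <- (td + curve$time_ms[1L]) %% cyc
    ord <- order(td)
    td <- td[ord]; g <- g[ord]
    g <- gaussian_smooth_values(g, cyc / m, sigma)
  }
  m <- length(g)
  dg <- circular_diff(g)

  # anchor: steepest acquired interval; refine within +/- one frame interval
  i_acq <- which.max(d_acq)
  t_anchor <- curve$time_ms[i_acq] + frame_interval_ms(curve) / 2
  off <- centered_mod(td - t_anchor, cyc)
  cand <- which(abs(off) <= frame_interval_ms(curve))
  i_star <- cand[which.max(dg[cand])]
  t_star <- td[i_star]

  # contiguous rising run around the steepest dense interval
  a <- i_star
  repeat {
    prev <- wrap_index(a - 1L, m)
    if (dg[prev] <= 0 || prev == i_star) break
    a <- prev
  }
  b <- wrap_index(i_star + 1L, m)
  while (dg[b] > 0 && b != i_star) b <- wrap_index(b + 1L, m)
  run <- if (a <= b) a:b else c(a:m, 1:b)

  # baseline tangent over the window preceding the upstroke
  back <- (t_star - td) %% cyc
  bl_idx <- which(back > 0 & back <= config$baseline_window_frac * cyc)
  if (!length(bl_idx)) {
    stop_input("baseline window contains no samples; curve too short")
  }
  bl_t <- t_star - back[bl_idx]          # unwrapped, ends at t_star
  if (config$baseline_fit_slope) {
    bl_fit <- lm.fit(cbind(1, bl_t), g[bl_idx])
    bl_slope <- unname(bl_fit$coefficients[2L])
    bl_int <- unname(bl_fit$coefficients[1L])
    if (abs(bl_slope) > config$max_baseline_slope) {
      abort(sprintf("baseline tangent slope %.3g exceeds the near-zero bound %.3g",
                    bl_slope, config$max_baseline_slope),
            class = "pwvttf_error_degenerate_tangents")
    }
    bl_r2 <- r_squared(g[bl_idx], bl_int + bl_slope * bl_t)
  } else {
    bl_slope <- 0
    bl_int <- mean(g[bl_idx])
    bl_r2 <- NA_real_
  }
  baseline <- new_tangent_fit(bl_slope, bl_int,
                              range(bl_t) %% cyc, bl_r2)

  # upslope regression window: rising-limb samples inside the flow band
  peak <- max(g)
  base_level <- bl_int + bl_slope * t_star
  lo <- base_level + config$upslope_band[1L] * (peak - base_level)
  hi <- base_level + config$upslope_band[2L] * (peak - base_level)
  sel <- run[g[run] >= lo & g[run] <= hi]
  if (length(sel) < config$min_upslope_points) {
    extra <- run[order(abs(match(run, run) - match(i_star, run)))]
    sel <- unique(c(sel, extra))[seq_len(min(length(run), config$min_upslope_points))]
  }
  if (length(sel) < 2L) {
    abort("no upstroke detected: rising region too short to fit a tangent",
          class = "pwvttf_error_no_upstroke")
  }
  tt <- t_star + centered_mod(td[sel] - t_star, cyc) # unwrapped fit times
  up_fit <- lm.fit(cbind(1, tt), g[sel])
  up_slope <- unname(up_fit$coefficients[2L])
  up_int <- unname(up_fit$coefficients[1L])
  if (!is.finite(up_slope) || up_slope <= 0) {
    abort("no upstroke detected: non-positive upslope tangent",
          class = "pwvttf_error_no_upstroke")
  }
  if (abs(up_slope - bl_slope) <=
      1e-9 * max(abs(up_slope), abs(bl_slope))) {
    abort("degenerate tangents: upslope and baseline are near-parallel",
          class = "pwvttf_error_degenerate_tangents")
  }
  upslope <- new_tangent_fit(up_slope, up_int, range(tt) %% cyc,
                             r_squared(g[sel], up_int + up_slope * tt))

  foot <- (bl_int - up_int) / (up_slope - bl_slope)
  structure(list(foot_time_ms = foot %% cyc,
                 upslope = upslope,
                 baseline = baseline,
                 cycle_ms = cyc),
            class = "foot_result")
}

#' @export
print.foot_result <- function(x, ...) {
  cat(sprintf("# Foot at %.3f ms (upslope %.4g ml/s/ms, baseline %.4g ml/s)\n",
              x$foot_time_ms, x$upslope$slope, x$baseline$intercept))
  invisible(x)
}

circular_diff <- function(f) c(diff(f), f[1L] - f[length(f)])

wrap_index <- function(i, n) ((i - 1L) %% n) + 1L

centered_mod <- function(x, cyc) ((x + cyc / 2) %% cyc) - cyc / 2

r_squared <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum((y - fitted)^2) / ss_tot
}

#' Transit time between two systolic feet
#'
#' The time delay between the feet of the proximal and distal flow curves,
#' taken modulo the cycle and mapped to `(-cycle/2, cycle/2]`. A
#' non-positive delay is non-physiologic (the wave cannot arrive distally
#' first); it is returned, but with a classed warning
#' (`pwvttf_warning_nonphysiologic`) carrying the value.
#'
#' @param proximal,distal `foot_result` objects (or foot times in ms).
#' @param cycle_ms Cycle length in ms; taken from the foot results when
#'   omitted (they must agree).
#' @return Transit time in ms.
#' @examples
#' transit_time(80, 205, cycle_ms = 1000)   # 125
#' transit_time(990, 15, cycle_ms = 1000)   # 25 (wrap-around)
#' @export
transit_time <- function(proximal, distal, cycle_ms = NULL) {
  get_foot <- function(x) {
    if (inherits(x, "foot_result")) x$foot_time_ms else check_number(x, "foot time")
  }
  if (is.null(cycle_ms)) {
    if (!inherits(proximal, "foot_result") || !inherits(distal, "foot_result")) {
      stop_input("`cycle_ms` is required when feet are given as plain numbers")
    }
    if (abs(proximal$cycle_ms - distal$cycle_ms) > 1e-9) {
      stop_input("proximal and distal feet come from different cycle lengths")
    }
    cycle_ms <- proximal$cycle_ms
  }
  dt <- (get_foot(distal) - get_foot(proximal)) %% cycle_ms
  if (dt > cycle_ms / 2) dt <- dt - cycle_ms
  if (dt <= 0) {
    warn(sprintf("non-physiologic transit time: %.3f ms", dt),
         class = "pwvttf_warning_nonphysiologic", delta_t_ms = dt)
  }
  dt
}

#' Pulse wave velocity from distance and transit time
#'
#' `pwv = distance / delta_t`; with distance in mm and time in ms the result
#' is in m/s directly.
#'
#' @param distance_mm Centre-line distance between flow planes in mm.
#' @param delta_t_ms Transit time in ms; must be positive.
#' @return PWV in m/s.
#' @examples
#' compute_pwv(250, 50)  # 5 m/s
#' @export
compute_pwv <- function(distance_mm, delta_t_ms) {
  check_number(distance_mm, "distance_mm")
  check_number(delta_t_ms, "delta_t_ms")
  if (distance_mm <= 0) stop_parameter("`distance_mm` must be positive")
  if (delta_t_ms <= 0) {
    abort(sprintf("non-physiologic transit time: %.3f ms", delta_t_ms),
          class = c("pwvttf_error_nonphysiologic", "pwvttf_error_parameter"),
          delta_t_ms = delta_t_ms)
  }
  distance_mm / delta_t_ms
}

#' Eddy-current baseline offset of a flow curve
#'
#' Estimates the constant background-phase (eddy-current) offset as the mean
#' flow during late diastole, 62.5–87.5 % of the cardiac cycle, when true
#' aortic flow is expected to be zero. Subtracting it re-zeroes late
#' diastole. The estimate is biased in significant aortic regurgitation,
#' where diastolic flow is genuinely non-zero — the reason
#' [apply_baseline_correction()] also accepts a manually chosen offset.
#'
#' @param curve A uniformly sampled [flow_curve()].
#' @param window Fractions of the cycle delimiting the late-diastolic
#'   window.
#' @return Offset in ml/s.
#' @export
auto_baseline_offset <- function(curve, window = c(0.625, 0.875)) {
  check_uniform(curve, "auto_baseline_offset()")
  cyc <- cycle_ms(curve)
  sel <- curve$time_ms >= window[1L] * cyc & curve$time_ms <= window[2L] * cyc
  if (!any(sel)) {
    stop_input("late-diastolic window contains no samples; curve too short")
  }
  mean(curve$flow_ml_s[sel])
}

#' Apply a baseline correction to a flow curve
#'
#' Subtracts a constant offset from the whole curve. With `offset = NULL`
#' (automatic mode) the offset comes from [auto_baseline_offset()]; a number
#' gives the manual mode.
#'
#' @param curve A [flow_curve()].
#' @param offset Offset in ml/s, or `NULL` for the automatic late-diastolic
#'   estimate.
#' @return The corrected [flow_curve()].
#' @export
apply_baseline_correction <- function(curve, offset = NULL) {
  if (is.null(offset)) offset <- auto_baseline_offset(curve)
  check_number(offset, "offset")
  flow_curve(curve$time_ms, curve$flow_ml_s - offset, cycle_ms(curve))
}

#' Measure pulse wave velocity from a pair of flow curves
#'
#' End-to-end time-to-foot measurement: optional baseline correction,
#' Gaussian smoothing, per-curve foot detection by intersecting tangents,
#' transit time and PWV. Full per-curve diagnostics are kept in the result.
#'
#' @param proximal,distal Uniformly sampled [flow_curve()]s sharing the same
#'   cycle length (ascending aorta and diaphragm level).
#' @param distance_mm Centre-line distance between the two flow planes in
#'   mm.
#' @param smoothing A [smoothing_spec()].
#' @param config A [ttf_config()].
#' @param baseline `"off"`, `"auto"` (late-diastolic estimate per curve) or
#'   `"manual"` with `baseline_offset`.
#' @param baseline_offset Offset(s) in ml/s for `baseline = "manual"`;
#'   length 1 (both curves) or 2 (proximal, distal).
#' @return A `pwv_result`: `pwv_m_s`, `delta_t_ms`, `distance_mm`,
#'   `proximal_foot`, `distal_foot`, `cycle_ms`. An error of class
#'   `pwvttf_error_nonphysiologic` is raised when the transit time is not
#'   positive.
#' @examples
#' pair <- make_phantom_pair(waveform_params(), pwv_true = 6,
#'                           distance_mm = 250, n_frames = 10000)
#' res <- measure_pwv(pair$proximal, pair$distal, distance_mm = 250)
#' glance(res)
#' @export
measure_pwv <- function(proximal, distal, distance_mm,
                        smoothing = smoothing_spec(sigma_frac = 0.025),
                        config = ttf_config(),
                        baseline = c("off", "auto", "manual"),
                        baseline_offset = NULL) {
  baseline <- match.arg(baseline)
  if (abs(cycle_ms(proximal) - cycle_ms(distal)) > 1e-9) {
    stop_input("proximal and distal curves must share the same cycle length")
  }
  check_number(distance_mm, "distance_mm", lower = .Machine$double.eps)
  if (baseline == "auto") {
    proximal <- apply_baseline_correction(proximal)
    distal <- apply_baseline_correction(distal)
  } else if (baseline == "manual") {
    if (is.null(baseline_offset) || !length(baseline_offset) %in% 1:2) {
      stop_parameter("`baseline = \"manual\"` needs `baseline_offset` of length 1 or 2")
    }
    off <- rep_len(as.numeric(baseline_offset), 2L)
    proximal <- apply_baseline_correction(proximal, off[1L])
    distal <- apply_baseline_correction(distal, off[2L])
  }
  with_curve <- function(curve, which) {
    withCallingHandlers(
      detect_foot(curve, smoothing = smoothing, config = config),
      error = function(e) {
        abort(sprintf("%s curve: %s", which, conditionMessage(e)),
              class = class(e)[1L], parent = e)
      })
  }
  prox_foot <- with_curve(proximal, "proximal")
  dist_foot <- with_curve(distal, "distal")
  dt <- suppressWarnings(transit_time(prox_foot, dist_foot))
  if (dt <= 0) {
    abort(sprintf("non-physiologic transit time: %.3f ms", dt),
          class = "pwvttf_error_nonphysiologic", delta_t_ms = dt)
  }
  structure(list(pwv_m_s = distance_mm / dt,
                 delta_t_ms = dt,
                 distance_mm = distance_mm,
                 proximal_foot = prox_foot,
                 distal_foot = dist_foot,
                 cycle_ms = cycle_ms(proximal)),
            class = "pwv_result")
}

#' @export
print.pwv_result <- function(x, ...) {
  cat(sprintf("# PWV %.3f m/s = %.1f mm / %.3f ms (feet %.3f -> %.3f ms)\n",
              x$pwv_m_s, x$distance_mm, x$delta_t_ms,
              x$proximal_foot$foot_time_ms, x$distal_foot$foot_time_ms))
  invisible(x)
}

#' Tidiers for PWV results
#'
#' `tidy()` returns one row per curve with the foot time and tangent
#' diagnostics; `glance()` returns a one-row summary with the transit time,
#' distance and PWV.
#'
#' @param x A `pwv_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pwv_result <- function(x, ...) {
  row <- function(which, foot) {
    tibble(curve = which,
           foot_time_ms = foot$foot_time_ms,
           upslope_slope = foot$upslope$slope,
           upslope_r_squared = foot$upslope$r_squared,
           baseline_level_ml_s = foot$baseline$intercept,
           baseline_slope = foot$baseline$slope)
  }
  dplyr::bind_rows(row("proximal", x$proximal_foot),
                   row("distal", x$distal_foot))
}

#' @rdname tidy.pwv_result
#' @export
glance.pwv_result <- function(x, ...) {
  tibble(pwv_m_s = x$pwv_m_s,
         delta_t_ms = x$delta_t_ms,
         distance_mm = x$distance_mm,
         cycle_ms = x$cycle_ms,
         proximal_foot_ms = x$proximal_foot$foot_time_ms,
         distal_foot_ms = x$distal_foot$foot_time_ms)
}
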