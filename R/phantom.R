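#' Acquired temporal resolution of a gated acquisition
#'
#' Cardiac cycle length divided by the number of genuinely acquired time
#' frames.
#'
#' @param n_frames Number of time frames per cycle (>= 1).
#' @param cycle_ms Cycle length in ms.
#' @return Temporal resolution in ms (full precision; tables round half-up
#'   to one decimal, the convention of printed clinical tables).
#' @examples
#' temporal_resolution(35, 1000)  # 28.57... -> printed as 28.6
#' @export
temporal_resolution <- function(n_frames, cycle_ms) {
  if (any(n_frames < 1) || any(n_frames != round(n_frames))) {
    stop_input("`n_frames` must be whole numbers >= 1")
  }
  check_number(cycle_ms, "cycle_ms", lower = .Machine$double.eps)
  cycle_ms / n_frames
}

#' Phantom experiment grid configuration
#'
#' Conditions for the temporal-resolution experiment: every combination of
#' true PWV and acquired frame count. Defaults reproduce the study design —
#' PWV 2–20 m/s in 10 steps of 2 m/s crossed with 20–40 frames per cycle
#' (21 steps), 210 conditions in total, a 250 mm plane distance and the
#' 60 bpm synthetic waveform evaluated on a 10 000-point dense grid.
#'
#' @param pwv_values True PWVs in m/s.
#' @param frame_counts Acquired frame counts per cycle.
#' @param distance_mm Flow-plane distance in mm.
#' @param waveform A [waveform_params()].
#' @param dense_n Dense evaluation grid size.
#' @param smoothing A [smoothing_spec()] used by the TTF measurement.
#' @param ttf A [ttf_config()].
#' @param filter Anti-aliasing filter for the downsampling step.
#' @return A `phantom_grid` list.
#' @export
phantom_grid <- function(pwv_values = seq(2, 20, by = 2),
                         frame_counts = 20:40,
                         distance_mm = 250,
                         waveform = waveform_params(),
                         dense_n = 10000,
                         smoothing = smoothing_spec(sigma_frac = 0.025),
                         ttf = ttf_config(),
                         filter = c("windowed_sinc", "ideal")) {
  stopifnot(inherits(waveform, "waveform_params"),
            inherits(smoothing, "smoothing_spec"),
            inherits(ttf, "ttf_config"))
  if (!length(pwv_values) || any(pwv_values <= 0)) {
    stop_parameter("`pwv_values` must be positive")
  }
  if (!length(frame_counts) || any(frame_counts < 4) ||
      any(frame_counts != round(frame_counts))) {
    stop_parameter("`frame_counts` must be whole numbers >= 4")
  }
  check_number(distance_mm, "distance_mm", lower = .Machine$double.eps)
  structure(list(pwv_values = as.numeric(pwv_values),
                 frame_counts = as.integer(frame_counts),
                 distance_mm = distance_mm,
                 waveform = waveform,
                 dense_n = check_count(dense_n, "dense_n", lower = 16L),
                 smoothing = smoothing,
                 ttf = ttf,
                 filter = match.arg(filter)),
            class = "phantom_grid")
}

#' Run the temporal-resolution phantom experiment
#'
#' For every (true PWV, frame count) condition: build the phantom curve pair
#' with the known injected shift, measure PWV with the time-to-foot method,
#' and record the signed and percentage error. Per-frame-count rows
#' aggregate the median signed error, the median and the maximum absolute
#' percentage error over all PWVs. A condition whose foot detection fails is
#' recorded as a failure in its row, not raised.
#'
#' @param config A [phantom_grid()].
#' @return A `phantom_experiment` list: `conditions` (one tibble row per
#'   condition), `errors` (one row per frame count, ascending), `config`.
#' @examples
#' \donttest{
#' exp <- run_phantom_experiment(phantom_grid())
#' exp$errors
#' determine_cutoff(exp$errors, tolerance_pct = 6)
#' }
#' @export
run_phantom_experiment <- function(config = phantom_grid()) {
  stopifnot(inherits(config, "phantom_grid"))
  cells <- tidyr_expand_grid(config$pwv_values, config$frame_counts)
  conditions <- purrr::pmap_dfr(cells, function(pwv_true, n_frames) {
    res <- tryCatch({
      pair <- make_phantom_pair(config$waveform, pwv_true,
                                config$distance_mm, n_frames,
                                dense_n = config$dense_n,
                                filter = config$filter)
      fit <- measure_pwv(pair$proximal, pair$distal, config$distance_mm,
                         smoothing = config$smoothing, config = config$ttf)
      tibble(shift_ms = pair$shift_ms, pwv_measured = fit$pwv_m_s,
             status = "ok")
    }, error = function(e) {
      tibble(shift_ms = config$distance_mm / pwv_true,
             pwv_measured = NA_real_, status = conditionMessage(e))
    })
    tibble(pwv_true = pwv_true, n_frames = as.integer(n_frames),
           temporal_resolution_ms = temporal_resolution(n_frames,
                                                        config$waveform$cycle_ms),
           res,
           error_m_s = res$pwv_measured - pwv_true,
           pct_error = 100 * (res$pwv_measured - pwv_true) / pwv_true)
  })
  errors <- conditions |>
    dplyr::group_by(.data$n_frames, .data$temporal_resolution_ms) |>
    dplyr::summarise(
      median_error_m_s = median(.data$error_m_s, na.rm = TRUE),
      median_abs_pct_error = median(abs(.data$pct_error), na.rm = TRUE),
      max_abs_pct_error = max_or_na(abs(.data$pct_error)),
      n_failed = sum(.data$status != "ok"),
      .groups = "drop") |>
    dplyr::arrange(.data$n_frames)
  structure(list(conditions = conditions, errors = errors, config = config),
            class = "phantom_experiment")
}

# expand.grid with predictable names and pwv varying fastest within frames
tidyr_expand_grid <- function(pwv_values, frame_counts) {
  tibble(pwv_true = rep(pwv_values, times = length(frame_counts)),
         n_frames = rep(frame_counts, each = length(pwv_values)))
}

# printed tables round half-up (31.25 -> 31.3), unlike base round()
round_half_up <- function(x, digits = 0L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

max_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else max(x)
}

#' @export
print.phantom_experiment <- function(x, ...) {
  cat(sprintf("# Phantom experiment: %d conditions (%d PWVs x %d frame counts), %d failed\n",
              nrow(x$conditions), length(x$config$pwv_values),
              length(x$config$frame_counts), sum(x$conditions$status != "ok")))
  print(x$errors, n = nrow(x$errors))
  invisible(x)
}

#' @rdname run_phantom_experiment
#' @param x A `phantom_experiment`.
#' @param ... Unused.
#' @export
tidy.phantom_experiment <- function(x, ...) as_tibble(x$conditions)

#' @rdname run_phantom_experiment
#' @export
glance.phantom_experiment <- function(x, ...) {
  tibble(n_conditions = nrow(x$conditions),
         n_failed = sum(x$conditions$status != "ok"),
         cutoff_n_frames = determine_cutoff(x$errors, tolerance_pct = 6),
         max_abs_pct_error = max_or_na(abs(x$conditions$pct_error)))
}

#' Frame-count cut-off for adequate temporal resolution
#'
#' The smallest frame count from which the PWV error stays within tolerance:
#' the smallest `n` such that `max_abs_pct_error <= tolerance_pct` for every
#' row with `n_frames >= n`. Formalises the plateau read off the error
#' curves. Returns `NA` (with a message) when no suffix of the frame-count
#' range qualifies.
#'
#' @param errors The `errors` tibble of a [run_phantom_experiment()] result
#'   (or the whole `phantom_experiment`), covering a contiguous frame-count
#'   range.
#' @param tolerance_pct Maximum tolerated absolute percentage error.
#' @return The cut-off frame count (integer), or `NA_integer_`.
#' @export
determine_cutoff <- function(errors, tolerance_pct = 6) {
  if (inherits(errors, "phantom_experiment")) errors <- errors$errors
  if (!is.data.frame(errors) || !nrow(errors)) {
    stop_input("`errors` must be a non-empty error table")
  }
  if (!all(c("n_frames", "max_abs_pct_error") %in% names(errors))) {
    stop_format("`errors` needs columns `n_frames` and `max_abs_pct_error`")
  }
  errors <- dplyr::arrange(errors, .data$n_frames)
  if (nrow(errors) > 1L && !all(diff(errors$n_frames) == 1L)) {
    stop_input("`errors` must cover a contiguous frame-count range")
  }
  check_number(tolerance_pct, "tolerance_pct", lower = 0)
  ok <- errors$max_abs_pct_error <= tolerance_pct & !is.na(errors$max_abs_pct_error)
  # smallest n whose entire suffix is within tolerance
  suffix_ok <- rev(cumprod(rev(ok))) > 0
  if (!any(suffix_ok)) {
    inform(sprintf("no frame count reaches a stable <= %g%% plateau", tolerance_pct))
    return(NA_integer_)
  }
  as.integer(errors$n_frames[which(suffix_ok)[1L]])
}
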