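#' Flow curve objects
#'
#' A flow curve is one cardiac cycle of volumetric flow sampled over time:
#' a tibble with columns `time_ms` (strictly increasing, within
#' `[0, cycle_ms)`) and `flow_ml_s`, carrying the cycle length as the
#' `cycle_ms` attribute. All measurement and resampling functions in pwvttf
#' operate on this object. Retrospectively gated acquisitions reconstruct
#' frames across the whole cycle, so the curve is treated as one period of a
#' periodic signal everywhere in the package.
#'
#' @param data A data frame with numeric columns `time_ms` and `flow_ml_s`
#'   (extra columns are dropped).
#' @param time_ms,flow_ml_s Numeric vectors of equal length (at least 4
#'   samples).
#' @param cycle_ms Cardiac cycle length in milliseconds.
#'
#' @return A `flow_curve`: a tibble with columns `time_ms`, `flow_ml_s` and
#'   attribute `cycle_ms`.
#' @examples
#' fc <- flow_curve(time_ms = seq(0, 975, by = 25),
#'                  flow_ml_s = sin(seq(0, 975, by = 25) / 1000 * 2 * pi),
#'                  cycle_ms = 1000)
#' cycle_ms(fc)
#' @export
flow_curve <- function(time_ms, flow_ml_s, cycle_ms) {
  new_flow_curve(tibble(time_ms = as.numeric(time_ms),
                        flow_ml_s = as.numeric(flow_ml_s)),
                 cycle_ms = cycle_ms)
}

#' @rdname flow_curve
#' @export
as_flow_curve <- function(data, cycle_ms) {
  if (!is.data.frame(data)) {
    stop_input("`data` must be a data frame with columns `time_ms` and `flow_ml_s`")
  }
  missing_cols <- setdiff(c("time_ms", "flow_ml_s"), names(data))
  if (length(missing_cols)) {
    stop_format(sprintf("missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  new_flow_curve(tibble(time_ms = as.numeric(data$time_ms),
                        flow_ml_s = as.numeric(data$flow_ml_s)),
                 cycle_ms = cycle_ms)
}

new_flow_curve <- function(data, cycle_ms) {
  check_number(cycle_ms, "cycle_ms", lower = .Machine$double.eps)
  n <- nrow(data)
  if (n < 4L) stop_input("a flow curve needs at least 4 samples")
  t <- data$time_ms
  f <- data$flow_ml_s
  if (anyNA(t) || anyNA(f) || !all(is.finite(t)) || !all(is.finite(f))) {
    bad <- which(!is.finite(t) | !is.finite(f))[1L]
    stop_format(sprintf("non-finite value at sample %d", bad))
  }
  d <- diff(t)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L]
    stop_format(sprintf(
      "`time_ms` must be strictly increasing; violated between samples %d and %d",
      bad, bad + 1L))
  }
  if (t[1L] < 0 || t[n] >= cycle_ms) {
    stop_format("`time_ms` must lie within [0, cycle_ms)")
  }
  structure(data, cycle_ms = as.numeric(cycle_ms),
            class = c("flow_curve", class(tibble())))
}

#' @rdname flow_curve
#' @param x A `flow_curve`.
#' @export
cycle_ms <- function(x) {
  out <- attr(x, "cycle_ms", exact = TRUE)
  if (is.null(out)) stop_input("`x` has no `cycle_ms` attribute; is it a flow_curve?")
  out
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("# Flow curve: %d frames over a %g ms cycle (%.1f ms spacing%s)\n",
              nrow(x), cycle_ms(x), cycle_ms(x) / nrow(x),
              if (is_uniform(x)) "" else ", non-uniform"))
  print(as_tibble(x), ...)
  invisible(x)
}

# uniform grid check: generator/resampler output has time_ms = i * cycle / n
is_uniform <- function(curve, tol = 1e-6) {
  t <- curve$time_ms
  n <- length(t)
  spacing <- cycle_ms(curve) / n
  expected <- t[1L] + spacing * (seq_len(n) - 1L)
  all(abs(t - expected) <= tol * spacing)
}

check_uniform <- function(curve, what = "this operation") {
  if (!is_uniform(curve)) {
    stop_input(sprintf("%s requires a uniformly sampled flow curve", what))
  }
  invisible(curve)
}

frame_interval_ms <- function(curve) cycle_ms(curve) / nrow(curve)

uniform_times <- function(n, cycle_ms) (seq_len(n) - 1L) * cycle_ms / n
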