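#' Velocity-map series
#'
#' Container for a through-plane phase-contrast velocity time series: a
#' 3D array `[x, y, frame]` of velocities in cm/s, the in-plane pixel
#' spacing in mm, the frame times in ms and the velocity-encoding limit.
#'
#' @param frames Numeric 3D array `[x, y, frame]` in cm/s.
#' @param pixel_spacing_mm Length-2 numeric, in-plane pixel size in mm.
#' @param frame_times_ms Strictly increasing frame times in ms.
#' @param cycle_ms Cardiac cycle length in ms.
#' @param venc_cm_s Velocity-encoding limit; all velocities must satisfy
#'   `|v| <= venc`.
#' @return A `velocity_series` list.
#' @export
velocity_series <- function(frames, pixel_spacing_mm, frame_times_ms,
                            cycle_ms, venc_cm_s = Inf) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_input("`frames` must be a 3D array [x, y, frame]")
  }
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0)) {
    stop_parameter("`pixel_spacing_mm` must be two positive numbers")
  }
  if (length(frame_times_ms) != dim(frames)[3L]) {
    stop_input("`frame_times_ms` length must match the number of frames")
  }
  if (any(diff(frame_times_ms) <= 0)) {
    stop_format("`frame_times_ms` must be strictly increasing")
  }
  check_number(cycle_ms, "cycle_ms", lower = .Machine$double.eps)
  if (is.finite(venc_cm_s) && max(abs(frames)) > venc_cm_s) {
    stop_input("velocities exceed `venc_cm_s`; aliased data?")
  }
  structure(list(frames = frames,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 frame_times_ms = as.numeric(frame_times_ms),
                 cycle_ms = as.numeric(cycle_ms),
                 venc_cm_s = venc_cm_s),
            class = "velocity_series")
}

#' Extract a flow curve from a velocity-map series and an ROI mask
#'
#' Integrates through-plane velocity over the vessel region of interest for
#' each frame: `flow(t) = sum(v[pixel, t]) * pixel_area`, with cm/s times
#' mm^2 converted to ml/s (factor 1e-2). The mask may be static (2D) or
#' per-frame (3D). Velocity sign is never flipped automatically; set
#' `flip_sign = TRUE` when positive phase encodes flow away from the
#' measurement direction of interest.
#'
#' @param series A [velocity_series()].
#' @param mask Logical/0-1 matrix matching the frame shape, or a 3D array
#'   with one mask per frame; every frame needs at least one foreground
#'   pixel.
#' @param flip_sign Negate velocities before integrating.
#' @return A [flow_curve()].
#' @examples
#' v <- array(10, dim = c(10, 10, 8))   # uniform 10 cm/s
#' s <- velocity_series(v, c(1, 1), seq(0, 875, by = 125), cycle_ms = 1000)
#' extract_flow_curve(s, matrix(TRUE, 10, 10))$flow_ml_s  # 10 ml/s each frame
#' @export
extract_flow_curve <- function(series, mask, flip_sign = FALSE) {
  stopifnot(inherits(series, "velocity_series"))
  dims <- dim(series$frames)
  if (is.matrix(mask)) {
    if (!all(dim(mask) == dims[1:2])) {
      stop_input("mask shape does not match the velocity frames")
    }
    masks <- array(as.logical(mask), dim = dims)
  } else if (is.array(mask) && length(dim(mask)) == 3L) {
    if (!all(dim(mask) == dims)) {
      stop_input("per-frame mask shape does not match the velocity series")
    }
    masks <- array(as.logical(mask), dim = dims)
  } else {
    stop_input("`mask` must be a matrix or a 3D array")
  }
  px_area_mm2 <- prod(series$pixel_spacing_mm)
  sgn <- if (isTRUE(flip_sign)) -1 else 1
  flow <- vapply(seq_len(dims[3L]), function(k) {
    m <- masks[, , k]
    if (!any(m)) stop_input(sprintf("mask frame %d has no foreground pixels", k))
    sgn * sum(series$frames[, , k][m]) * px_area_mm2 * 1e-2
  }, numeric(1L))
  flow_curve(series$frame_times_ms, flow, series$cycle_ms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a velocity series and ROI mask from NIfTI volumes
#'
#' Reads a 3D NIfTI volume of through-plane velocities (frames stacked along
#' the third axis) and, optionally, a mask volume (2D static or 3D
#' per-frame). Requires the RNifti package.
#'
#' @param velocity_path Path to the velocity NIfTI (values in cm/s).
#' @param mask_path Optional path to the binary ROI NIfTI.
#' @param pixel_spacing_mm In-plane pixel spacing; defaults to the NIfTI
#'   header's pixdim.
#' @param frame_times_ms Frame times; defaults to uniform sampling of
#'   `cycle_ms`.
#' @param cycle_ms Cardiac cycle length in ms.
#' @param venc_cm_s Velocity-encoding limit.
#' @return A list with elements `series` ([velocity_series()]) and `mask`
#'   (or `NULL`).
#' @export
read_velocity_series <- function(velocity_path, mask_path = NULL,
                                 pixel_spacing_mm = NULL,
                                 frame_times_ms = NULL,
                                 cycle_ms, venc_cm_s = Inf) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop_input("reading NIfTI volumes requires the RNifti package")
  }
  img <- RNifti::readNifti(velocity_path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3L) stop_format("velocity volume must be 3D [x, y, frame]")
  if (is.null(pixel_spacing_mm)) {
    pixel_spacing_mm <- RNifti::pixdim(img)[1:2]
  }
  if (is.null(frame_times_ms)) {
    frame_times_ms <- uniform_times(dim(arr)[3L], cycle_ms)
  }
  series <- velocity_series(arr, pixel_spacing_mm, frame_times_ms,
                            cycle_ms, venc_cm_s)
  mask <- NULL
  if (!is.null(mask_path)) {
    mimg <- RNifti::readNifti(mask_path)
    mask <- array(as.numeric(mimg) > 0.5, dim = dim(mimg))
    if (length(dim(mask)) == 3L && dim(mask)[3L] == 1L) mask <- mask[, , 1L]
    if (length(dim(mask) %||% integer()) == 2L) mask <- as.matrix(mask)
  }
  list(series = series, mask = mask)
}
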