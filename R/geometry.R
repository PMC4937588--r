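#' Aortic centre-line travel distance
#'
#' The pulse-wave travel distance is measured along the aortic centre-line
#' between the ascending-aorta and diaphragm-level flow planes. The
#' centre-line is an ordered polyline of 3D points in patient-space mm
#' (first point on the proximal plane, last on the distal plane).
#' `method = "polyline"` sums Euclidean segment lengths;
#' `method = "spline"` fits a natural cubic spline through the points
#' (chord-length parameterised) and integrates its arc length on a dense
#' grid — useful when the centre-line was clicked sparsely by hand.
#'
#' @param points A data frame with numeric columns `x_mm`, `y_mm`, `z_mm`
#'   (at least 2 rows, consecutive points distinct).
#' @param method `"polyline"` (default) or `"spline"`.
#' @param spline_n Number of dense arc samples for the spline method.
#' @return Length in mm.
#' @examples
#' centerline_length(data.frame(x_mm = c(0, 100, 250), y_mm = 0, z_mm = 0))
#' @export
centerline_length <- function(points, method = c("polyline", "spline"),
                              spline_n = 2000) {
  method <- match.arg(method)
  points <- check_centerline(points)
  xyz <- as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
  seg <- sqrt(rowSums(diff(xyz)^2))
  if (method == "polyline" || nrow(xyz) < 4L) {
    return(sum(seg))
  }
  s <- c(0, cumsum(seg))          # chord-length parameter
  s_dense <- seq(0, s[length(s)], length.out = spline_n)
  dense <- vapply(1:3, function(j) {
    splinefun(s, xyz[, j], method = "natural")(s_dense)
  }, numeric(spline_n))
  sum(sqrt(rowSums(diff(dense)^2)))
}

check_centerline <- function(points) {
  if (!is.data.frame(points)) stop_input("`points` must be a data frame")
  missing_cols <- setdiff(c("x_mm", "y_mm", "z_mm"), names(points))
  if (length(missing_cols)) {
    stop_format(sprintf("centre-line is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  xyz <- as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
  if (nrow(xyz) < 2L) stop_input("a centre-line needs at least 2 points")
  if (anyNA(xyz) || !all(is.finite(xyz))) {
    stop_format("centre-line contains non-finite coordinates")
  }
  seg <- sqrt(rowSums(diff(xyz)^2))
  if (any(seg == 0)) {
    stop_input(sprintf("consecutive centre-line points %d and %d coincide",
                       which(seg == 0)[1L], which(seg == 0)[1L] + 1L))
  }
  tibble(x_mm = xyz[, 1L], y_mm = xyz[, 2L], z_mm = xyz[, 3L])
}

#' Read or write a centre-line file
#'
#' Delimited text with one point per row and columns `x_mm`, `y_mm`, `z_mm`.
#'
#' @param path File path.
#' @param points A centre-line data frame.
#' @return `read_centerline()` returns a tibble of points;
#'   `write_centerline()` returns `points` invisibly.
#' @export
read_centerline <- function(path) {
  check_centerline(readr::read_tsv(path, comment = "#",
                                   show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_centerline
#' @export
write_centerline <- function(points, path) {
  points <- check_centerline(points)
  readr::write_tsv(points, path, progress = FALSE)
  invisible(points)
}
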