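#' Read and write flow-curve files
#'
#' The interchange format is two-column tab-delimited text with a header
#' `time_ms  flow_ml_s` preceded by a comment line carrying the cycle
#' length:
#'
#' ```
#' # cycle_ms = 1000
#' time_ms	flow_ml_s
#' 0	0
#' 25	12.5
#' ...
#' ```
#'
#' Writing and re-reading reproduces times and flows to full double
#' precision. Malformed input (missing columns, duplicate or non-increasing
#' times, non-finite values) raises a format error naming the offending
#' line.
#'
#' @param path File path.
#' @param curve A [flow_curve()].
#' @return `read_flow_curve()` returns a [flow_curve()];
#'   `write_flow_curve()` returns `curve` invisibly.
#' @export
read_flow_curve <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  lines <- readLines(path, n = 5L)
  header <- grep("^#", lines, value = TRUE)
  m <- regmatches(header, regexec("cycle_ms\\s*=\\s*([0-9.eE+-]+)", header))
  cyc <- NULL
  for (g in m) if (length(g) == 2L) cyc <- as.numeric(g[2L])
  if (is.null(cyc) || is.na(cyc)) {
    stop_format(sprintf("%s: missing `# cycle_ms = <value>` comment line", path))
  }
  data <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  n_header_lines <- sum(grepl("^#", readLines(path))) + 1L
  tryCatch(
    as_flow_curve(data, cycle_ms = cyc),
    pwvttf_error_format = function(e) {
      msg <- conditionMessage(e)
      idx <- regmatches(msg, regexec("samples \\d+ and (\\d+)", msg))[[1L]]
      if (length(idx) < 2L) {
        idx <- regmatches(msg, regexec("sample (\\d+)", msg))[[1L]]
      }
      line <- if (length(idx) == 2L) {
        sprintf(" (line %d)", as.integer(idx[2L]) + n_header_lines)
      } else ""
      stop_format(sprintf("%s: %s%s", path, msg, line))
    })
}

#' @rdname read_flow_curve
#' @export
write_flow_curve <- function(curve, path) {
  stopifnot(inherits(curve, "flow_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cycle_ms = %s",
                     format(cycle_ms(curve), digits = 17)), con)
  writeLines("time_ms\tflow_ml_s", con)
  writeLines(sprintf("%s\t%s",
                     format(curve$time_ms, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     format(curve$flow_ml_s, digits = 17, trim = TRUE)),
             con)
  invisible(curve)
}

#' Write a phantom error table
#'
#' Tab-delimited analogue of the per-frame-count error table: frame count,
#' temporal resolution (one decimal), median signed error, median and
#' maximum absolute percentage error.
#'
#' @param experiment A `phantom_experiment`.
#' @param path File path.
#' @return The written tibble, invisibly.
#' @export
write_error_table <- function(experiment, path) {
  stopifnot(inherits(experiment, "phantom_experiment"))
  out <- experiment$errors |>
    dplyr::transmute(
      n_frames = .data$n_frames,
      temporal_resolution_ms = round_half_up(.data$temporal_resolution_ms, 1L),
      median_error_m_s = .data$median_error_m_s,
      median_abs_pct_error = .data$median_abs_pct_error,
      max_abs_pct_error = .data$max_abs_pct_error,
      n_failed = .data$n_failed)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
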