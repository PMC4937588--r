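#' Plot a flow curve
#'
#' @param object A [flow_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flow_curve
#' @export
autoplot.flow_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_ms, y = .data$flow_ml_s)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time (ms)", y = "Flow (ml/s)") +
    ggplot2::theme_minimal()
}

#' Plot a PWV measurement with its tangents and feet
#'
#' Superimposes the two flow curves and marks the detected feet; the
#' horizontal span between the feet is the transit time.
#'
#' @param object A `pwv_result` from [measure_pwv()].
#' @param proximal,distal Optionally, the measured curves to draw behind the
#'   feet.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pwv_result
#' @export
autoplot.pwv_result <- function(object, proximal = NULL, distal = NULL, ...) {
  feet <- tibble(curve = c("proximal", "distal"),
                 foot_time_ms = c(object$proximal_foot$foot_time_ms,
                                  object$distal_foot$foot_time_ms))
  p <- ggplot2::ggplot()
  if (!is.null(proximal) && !is.null(distal)) {
    curves <- dplyr::bind_rows(
      dplyr::mutate(as_tibble(proximal), curve = "proximal"),
      dplyr::mutate(as_tibble(distal), curve = "distal"))
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$time_ms, y = .data$flow_ml_s,
                   colour = .data$curve))
  }
  p +
    ggplot2::geom_vline(data = feet,
                        ggplot2::aes(xintercept = .data$foot_time_ms,
                                     colour = .data$curve),
                        linetype = "dashed") +
    ggplot2::labs(x = "Time (ms)", y = "Flow (ml/s)", colour = NULL,
                  title = sprintf("PWV %.2f m/s (Δt %.1f ms over %.0f mm)",
                                  object$pwv_m_s, object$delta_t_ms,
                                  object$distance_mm)) +
    ggplot2::theme_minimal()
}

#' Plot phantom-experiment errors against frame count
#'
#' Median percentage PWV error per frame count for a subset of true PWVs,
#' with the maximum-absolute-percentage-error envelope; the analogue of the
#' temporal-resolution error figure.
#'
#' @param object A `phantom_experiment`.
#' @param pwv_show True PWVs to draw individually.
#' @param tolerance_pct Horizontal guides at +/- this percentage.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phantom_experiment
#' @export
autoplot.phantom_experiment <- function(object, pwv_show = c(2, 8, 14, 20),
                                        tolerance_pct = 6, ...) {
  cond <- dplyr::filter(object$conditions, .data$pwv_true %in% pwv_show)
  cutoff <- determine_cutoff(object$errors, tolerance_pct)
  p <- ggplot2::ggplot(cond,
                       ggplot2::aes(x = .data$n_frames, y = .data$pct_error,
                                    colour = factor(.data$pwv_true))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-tolerance_pct, tolerance_pct),
                        colour = "grey60") +
    ggplot2::labs(x = "Time frames per cycle", y = "PWV error (%)",
                  colour = "True PWV (m/s)") +
    ggplot2::theme_minimal()
  if (!is.na(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, colour = "grey60")
  }
  p
}

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (a - b)") +
    ggplot2::theme_minimal()
}
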