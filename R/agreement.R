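#' Bland-Altman agreement analysis
#'
#' Agreement between two methods (or observers) measuring the same quantity
#' on the same subjects: per-pair differences `d = a - b`, the bias
#' (mean difference), the sample standard deviation of the differences, and
#' the 95 % limits of agreement `bias +/- 1.96 * sd`.
#'
#' @param data A data frame holding the paired measurements.
#' @param a,b Columns of `data` (tidy evaluation) with the two methods'
#'   values; same units, element-wise paired, at least 2 pairs.
#' @return A `bland_altman` object; `glance()` gives a one-row summary
#'   (`n`, `bias`, `sd`, `loa_lower`, `loa_upper`), `tidy()` the per-pair
#'   means and differences, `autoplot()` the Bland-Altman plot.
#' @examples
#' d <- data.frame(cmr = c(4.2, 5.0, 6.1), at = c(5.3, 6.2, 7.1))
#' glance(bland_altman(d, at, cmr))
#' @export
bland_altman <- function(data, a, b) {
  if (!is.data.frame(data)) stop_input("`data` must be a data frame")
  va <- rlang::eval_tidy(rlang::enquo(a), data)
  vb <- rlang::eval_tidy(rlang::enquo(b), data)
  if (!is.numeric(va) || !is.numeric(vb) || length(va) != length(vb)) {
    stop_input("`a` and `b` must be numeric columns of equal length")
  }
  if (length(va) < 2L) stop_input("Bland-Altman needs at least 2 pairs")
  if (anyNA(va) || anyNA(vb)) stop_input("paired measurements contain NA")
  d <- va - vb
  bias <- mean(d)
  s <- sd(d)
  structure(list(pairs = tibble(a = va, b = vb,
                                mean = (va + vb) / 2, difference = d),
                 n = length(d),
                 bias = bias,
                 sd = s,
                 loa_lower = bias - 1.96 * s,
                 loa_upper = bias + 1.96 * s),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("# Bland-Altman (n = %d): bias %.3f +/- %.3f, 95%% LoA [%.3f, %.3f]\n",
              x$n, x$bias, x$sd, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @rdname bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd = x$sd,
         loa_lower = x$loa_lower, loa_upper = x$loa_upper)
}
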