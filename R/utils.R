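# shared helpers

#' Trapezoidal area under a monthly survival curve, in years
#'
#' @param s survival probabilities on a grid of consecutive months starting
#'   at month 0.
#' @return area under the curve in years (month step = 1/12 year).
#' @keywords internal
trapz_years <- function(s) {
  n <- length(s)
  if (n < 2L) return(0)
  (sum(s) - (s[1L] + s[n]) / 2) / 12
}

#' Format a count with its percentage of a total
#'
#' Renders `"6,998 (16.8%)"`-style strings: thousands separators and the
#' percentage rounded to one decimal, the convention used in the result
#' tables.
#'
#' @param count integer count.
#' @param total integer total (> 0).
#' @return character scalar.
#' @export
#' @examples
#' format_count_pct(6998, 41649)
format_count_pct <- function(count, total) {
  stopifnot(total > 0, count >= 0, count <= total)
  sprintf("%s (%.1f%%)", formatC(count, format = "d", big.mark = ","),
          round(100 * count / total, 1))
}

# integer check tolerant of double storage
is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
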