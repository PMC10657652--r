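#' Monthly-grid survival curve
#'
#' The common container for observed (Kaplan-Meier), reference (life-table)
#' and extrapolated survival functions. Time is measured in whole months
#' since the index date (diagnosis), with a grid step of exactly one month.
#'
#' @param month integer vector `0, 1, 2, ...` (consecutive, starting at 0).
#' @param survival survival probabilities; `survival[month == 0]` must be 1
#'   and the sequence must be nonincreasing within `[0, 1]`.
#' @param type one of `"observed"`, `"reference"`, `"extrapolated"`.
#' @param n_at_risk,n_events,n_censored optional counts (observed curves).
#' @return a data frame of class `"survival_curve"` with attribute
#'   `curve_type`.
#' @export
survival_curve <- function(month, survival, type = c("observed", "reference",
                                                     "extrapolated"),
                           n_at_risk = NULL, n_events = NULL,
                           n_censored = NULL) {
  type <- match.arg(type)
  month <- as.integer(month)
  if (length(month) < 1L || month[1L] != 0L ||
      (length(month) > 1L && any(diff(month) != 1L)))
    stop("'month' must be consecutive integers starting at 0")
  if (length(survival) != length(month))
    stop("'survival' and 'month' lengths differ")
  if (abs(survival[1L] - 1) > 1e-12)
    stop("survival at month 0 must equal 1")
  if (any(survival < -1e-12) || any(survival > 1 + 1e-12))
    stop("survival probabilities outside [0, 1]")
  if (any(diff(survival) > 1e-9))
    stop("survival curve must be nonincreasing")
  survival <- pmin(pmax(survival, 0), 1)
  out <- data.frame(month = month, survival = survival)
  if (!is.null(n_at_risk))  out$n_at_risk  <- as.integer(n_at_risk)
  if (!is.null(n_events))   out$n_events   <- as.integer(n_events)
  if (!is.null(n_censored)) out$n_censored <- as.integer(n_censored)
  class(out) <- c("survival_curve", "data.frame")
  attr(out, "curve_type") <- type
  out
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve: %s, %d months, S(end) = %.4g>\n",
              attr(x, "curve_type"), max(x$month), x$survival[nrow(x)]))
  invisible(x)
}

#' Write a survival curve to CSV
#'
#' Columns `month,survival` plus `n_at_risk,n_events` when present.
#'
#' @param curve a [survival_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survival_curve <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  keep <- intersect(c("month", "survival", "n_at_risk", "n_events"),
                    names(curve))
  write.csv(as.data.frame(curve)[keep], path, row.names = FALSE)
  invisible(path)
}
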