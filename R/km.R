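# Kaplan-Meier product-limit estimation on the monthly grid.

#' Kaplan-Meier survival curve on the monthly grid
#'
#' Product-limit estimate `S(t) = prod_{u <= t} (1 - d_u / n_u)` with deaths
#' assumed to precede censorings within a month (so a patient censored in
#' month `t` is still at risk for the deaths of month `t`). The curve is
#' defined up to the largest follow-up time in the stratum.
#'
#' @param records patient records (see [validate_records()]).
#' @param stratum `NULL` (all records), a logical vector over rows, or a
#'   predicate `function(records) -> logical`.
#' @return an `"observed"` [survival_curve()] with `n_at_risk`, `n_events`
#'   and `n_censored` columns.
#' @export
fit_km <- function(records, stratum = NULL) {
  validate_records(records)
  recs <- subset_stratum(records, stratum)
  if (nrow(recs) == 0L) stop("empty stratum: no records to fit")
  fu <- as.integer(round(recs$follow_up_months))
  ev <- recs$event
  N <- length(fu)
  Tmax <- max(fu)
  if (Tmax == 0L)
    return(survival_curve(0L, 1, type = "observed", n_at_risk = N,
                          n_events = 0L, n_censored = sum(ev == 0)))
  d <- tabulate(fu[ev == 1], nbins = Tmax)
  cns <- tabulate(fu[ev == 0], nbins = Tmax)
  cnt <- tabulate(fu + 1L, nbins = Tmax + 1L)  # counts of fu = 0..Tmax
  # at risk at month t = #{fu >= t}; cumsum(cnt)[t] counts fu <= t - 1
  n_risk <- N - cumsum(cnt)[seq_len(Tmax)]
  s <- cumprod(1 - d / n_risk)
  survival_curve(0:Tmax, c(1, s), type = "observed",
                 n_at_risk = c(N, n_risk), n_events = c(0L, d),
                 n_censored = c(sum(fu == 0 & ev == 0), cns))
}

# resolve a stratum argument into a row subset
subset_stratum <- function(records, stratum) {
  if (is.null(stratum)) return(records)
  sel <- if (is.function(stratum)) stratum(records) else stratum
  if (!is.logical(sel) || length(sel) != nrow(records))
    stop("'stratum' must be NULL, a logical vector over rows, or a predicate")
  out <- records[which(sel), , drop = FALSE]
  attr(out, "cost_currency") <- attr(records, "cost_currency")
  out
}
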