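# Healthcare cost estimation: mean monthly cost among survivors, CPI
# adjustment to base-year USD, trailing-window smoothing with carry-forward
# into the extrapolated tail, and survival-weighted discounted lifetime cost.

#' Consumer price index series
#'
#' @param df data frame (or CSV path with columns `year,index`); values must
#'   be positive and the base year present.
#' @param base_year base year of the analysis currency. Default 2017.
#' @return data frame of class `"cpi_series"`.
#' @export
cpi_series <- function(df, base_year = 2017L) {
  if (is.character(df) && length(df) == 1L)
    df <- read.csv(df, stringsAsFactors = FALSE)
  stopifnot(all(c("year", "index") %in% names(df)))
  if (any(df$index <= 0)) stop("CPI index values must be positive")
  if (!base_year %in% df$year)
    stop("CPI series must contain the base year ", base_year)
  out <- as.data.frame(df[c("year", "index")])
  attr(out, "base_year") <- as.integer(base_year)
  class(out) <- c("cpi_series", "data.frame")
  out
}

#' CPI-adjust nominal TWD amounts to base-year USD
#'
#' `amount * (CPI_base / CPI_year) / twd_per_usd`; with the defaults this
#' converts nominal TWD to 2017 USD at 1 USD = 30.44 TWD.
#'
#' @param amount numeric amounts in nominal TWD.
#' @param year calendar year each amount was incurred (recycled).
#' @param cpi a [cpi_series()].
#' @param twd_per_usd exchange-rate constant. Default 30.44.
#' @return amounts in base-year USD.
#' @export
#' @examples
#' cpi <- cpi_series(data.frame(year = 2016:2017, index = c(99, 100)))
#' cpi_adjust(3044, 2017, cpi)  # 100 USD
cpi_adjust <- function(amount, year, cpi, twd_per_usd = 30.44) {
  stopifnot(inherits(cpi, "cpi_series"))
  i <- match(rep_len(year, length(amount)), cpi$year)
  if (anyNA(i))
    stop("CPI series missing year(s): ",
         paste(unique(year[is.na(match(year, cpi$year))]), collapse = ", "))
  base <- cpi$index[match(attr(cpi, "base_year"), cpi$year)]
  amount * (base / cpi$index[i]) / twd_per_usd
}

#' CPI-adjust the monthly cost vectors of a cohort
#'
#' Converts each patient's nominal-TWD monthly costs to base-year USD, using
#' the calendar year in which each month falls. Retags the cohort's cost
#' currency so downstream cost estimation accepts it.
#'
#' @param records patient records with a `costs` list column tagged `"TWD"`.
#' @param cpi a [cpi_series()].
#' @inheritParams cpi_adjust
#' @return `records` with adjusted costs, tagged `"USD<base year>"`.
#' @export
adjust_costs <- function(records, cpi, twd_per_usd = 30.44) {
  cur <- attr(records, "cost_currency")
  if (is.null(cur) || cur != "TWD")
    stop("adjust_costs() expects costs tagged \"TWD\"; got ",
         cur %||% "untagged")
  base_year <- attr(cpi, "base_year")
  for (i in seq_len(nrow(records))) {
    v <- records$costs[[i]]
    if (!length(v)) next
    t <- seq_along(v) - 1L
    yr <- records$dx_year[i] + (records$dx_month[i] - 1L + t) %/% 12L
    records$costs[[i]] <- cpi_adjust(v, yr, cpi, twd_per_usd)
  }
  attr(records, "cost_currency") <- paste0("USD", base_year)
  records
}

#' Mean monthly cost among surviving patients
#'
#' `c_raw(t) = sum_i cost_i(t) / #\{i alive and under observation at t\}`.
#' A patient with follow-up `f` contributes to the denominator of months
#' `0 .. f - 1`; absent cost entries count as zero in the numerator. The
#' curve spans months with at least one contributor.
#'
#' @param records patient records with a `costs` list column in analysis
#'   currency (`"USD2017"` by default; un-adjusted `"TWD"` raises an error,
#'   see [adjust_costs()]).
#' @param stratum as in [fit_km()].
#' @param currency required currency tag. Default `"USD2017"`.
#' @return data frame of class `"cost_curve"` with columns `month`, `cost`
#'   (mean among survivors), `n_contributing`.
#' @export
mean_monthly_cost <- function(records, stratum = NULL, currency = "USD2017") {
  validate_records(records)
  cur <- attr(records, "cost_currency")
  if (is.null(cur) || cur != currency)
    stop("cost currency is ", cur %||% "untagged", " but the analysis ",
         "requires ", currency, "; CPI-adjust first (see adjust_costs)")
  recs <- subset_stratum(records, stratum)
  if (nrow(recs) == 0L) stop("empty stratum")
  if (is.null(recs$costs)) stop("records carry no cost vectors")
  fu <- recs$follow_up_months
  Tmax <- max(fu)
  if (Tmax == 0L) stop("no observed months with cost contributions")
  n_contrib <- vapply(seq_len(Tmax) - 1L,
                      function(t) sum(fu > t), integer(1))
  total <- numeric(Tmax)
  for (v in recs$costs) {
    if (length(v)) total[seq_along(v)] <- total[seq_along(v)] + v
  }
  out <- data.frame(month = seq_len(Tmax) - 1L, cost = total / n_contrib,
                    n_contributing = n_contrib)
  class(out) <- c("cost_curve", "data.frame")
  attr(out, "currency") <- currency
  out
}

#' Smooth a cost curve and extend it over the lifetime grid
#'
#' Trailing weighted mean of the mean-monthly-cost curve over the previous
#' `window_months` months (weights proportional to the number of
#' contributing patients, i.e. precision weighting; no future months enter).
#' Months beyond the observed window carry the last smoothed value forward —
#' a deliberately conservative plateau for the unobserved tail.
#'
#' @param c_raw a `"cost_curve"` from [mean_monthly_cost()].
#' @param window_months trailing window length. Default 12.
#' @param horizon_months last month of the lifetime grid (e.g. the stop
#'   month of an [rolling_extrapolate()] result).
#' @return a `"cost_curve"` data frame with columns `month`, `cost`,
#'   `source` (`observed`/`extrapolated`) spanning months
#'   `0 .. horizon_months`.
#' @export
smooth_and_extend_cost <- function(c_raw, window_months = 12L,
                                   horizon_months) {
  stopifnot(inherits(c_raw, "cost_curve"))
  Tobs <- nrow(c_raw)
  if (Tobs < window_months)
    stop("smoothing window larger than the observed cost span")
  w <- c_raw$n_contributing
  cw <- c_raw$cost * w
  smoothed <- vapply(seq_len(Tobs), function(i) {
    j <- max(1L, i - window_months + 1L):i
    sum(cw[j]) / sum(w[j])
  }, numeric(1))
  H <- as.integer(horizon_months)
  if (H < Tobs - 1L) {
    smoothed <- smoothed[seq_len(H + 1L)]
    src <- rep("observed", H + 1L)
  } else {
    smoothed <- c(smoothed, rep(smoothed[Tobs], H - Tobs + 1L))
    src <- c(rep("observed", Tobs), rep("extrapolated", H - Tobs + 1L))
  }
  out <- data.frame(month = 0:H, cost = smoothed, source = src)
  class(out) <- c("cost_curve", "data.frame")
  attr(out, "currency") <- attr(c_raw, "currency")
  out
}

#' Survival-weighted discounted lifetime healthcare cost
#'
#' `lifetime_cost = sum_t S(t) * c(t) * (1 + r)^(-t/12)`, discounting from
#' the diagnosis month. Life expectancy (trapezoidal area of `S`, years) and
#' its discounted analogue are computed on the same grid, and the cost per
#' life-year is reported under both conventions (divided by undiscounted and
#' by discounted life expectancy).
#'
#' @param surv data frame with columns `month`, `survival` over the lifetime
#'   grid (e.g. `curve` of an [rolling_extrapolate()] result).
#' @param cost_curve smoothed `"cost_curve"` on the identical grid.
#' @param discount_rate annual discount rate. Default 0.03.
#' @return object of class `"lifetime_cost_result"`: list with
#'   `lifetime_cost`, `LE`, `LE_discounted`, `cost_per_life_year`,
#'   `cost_per_discounted_life_year`, `discount_rate`, `currency`.
#' @export
lifetime_cost <- function(surv, cost_curve, discount_rate = 0.03) {
  if (!identical(as.integer(surv$month), as.integer(cost_curve$month)))
    stop("grid mismatch between survival and cost curves")
  stopifnot(discount_rate >= 0)
  t <- surv$month
  disc <- (1 + discount_rate)^(-t / 12)
  total <- sum(surv$survival * cost_curve$cost * disc)
  le <- trapz_years(surv$survival)
  le_d <- trapz_years(surv$survival * disc)
  structure(list(lifetime_cost = total, LE = le, LE_discounted = le_d,
                 cost_per_life_year = total / le,
                 cost_per_discounted_life_year = total / le_d,
                 discount_rate = discount_rate,
                 currency = attr(cost_curve, "currency") %||% "USD2017"),
            class = "lifetime_cost_result")
}

#' @export
print.lifetime_cost_result <- function(x, ...) {
  cat(sprintf(paste0("<lifetime_cost_result: %s %.0f (discount %.1f%%/y);",
                     " %.0f per life-year, %.0f per discounted life-year>\n"),
              x$currency, x$lifetime_cost, 100 * x$discount_rate,
              x$cost_per_life_year, x$cost_per_discounted_life_year))
  invisible(x)
}
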