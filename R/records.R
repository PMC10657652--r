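# Patient records: one row per subject with demographics, diagnosis date,
# follow-up in whole months, death/censor indicator, stratum labels and
# (optionally) a per-month cost vector held in the list column `costs`.
#
# Conventions (declared, since claims data are monthly):
#   * month 0 is the diagnosis month; a death during the diagnosis month is
#     recorded as follow_up_months = 1, event = 1 (no zero-length intervals);
#   * follow_up_months = t, event = 1 means death in the interval (t-1, t];
#   * costs[[i]] has length <= follow_up_months (month 0 first): costs are
#     only observed while the patient is alive and under observation.

#' Validate a patient records data frame
#'
#' @param records data frame with columns `id`, `sex` (`"F"`/`"M"`),
#'   `age_at_dx`, `dx_year`, `dx_month` (1-12), `follow_up_months` (>= 0),
#'   `event` (1 = death, 0 = censored) and optionally `depression`
#'   (`"none"`/`"major"`/`"minor"`), further stratum columns and a `costs`
#'   list column.
#' @return `records`, invisibly, after validation.
#' @export
validate_records <- function(records) {
  need <- c("id", "sex", "age_at_dx", "dx_year", "dx_month",
            "follow_up_months", "event")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("patient records missing column(s): ", paste(miss, collapse = ", "))
  if (!all(records$sex %in% c("F", "M")))
    stop("'sex' must be \"F\" or \"M\"")
  if (!all(records$dx_month %in% 1:12))
    stop("'dx_month' must lie in 1..12")
  if (!is_whole(records$follow_up_months) || any(records$follow_up_months < 0))
    stop("'follow_up_months' must be non-negative integers")
  if (!all(records$event %in% c(0, 1)))
    stop("'event' must be 0 (censored) or 1 (death)")
  if (any(records$event == 1 & records$follow_up_months < 1))
    stop("deaths must have follow_up_months >= 1 (death in the diagnosis ",
         "month is recorded as follow_up_months = 1)")
  if ("depression" %in% names(records) &&
      !all(records$depression %in% c("none", "major", "minor")))
    stop("'depression' must be one of none/major/minor")
  if ("costs" %in% names(records)) {
    len <- lengths(records$costs)
    if (any(len > records$follow_up_months + 1L))
      stop("cost vectors longer than the observed follow-up")
    if (any(vapply(records$costs, function(x) any(x < 0), logical(1))))
      stop("negative cost entries")
  }
  invisible(records)
}

#' Read patient records from CSV
#'
#' Expects columns
#' `id,sex,age_at_dx,dx_year,dx_month,follow_up_months,event,depression`
#' (extra stratum columns are carried through).
#'
#' @param path CSV file path.
#' @return validated records data frame.
#' @export
read_patients <- function(path) {
  validate_records(read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(sex = "character")))
}

#' Attach a long-format cost table to patient records
#'
#' @param records validated patient records.
#' @param cost_long data frame (or CSV path) with columns `id,month,cost`;
#'   months are 0-based and must not reach beyond each patient's follow-up;
#'   months absent from the table count as zero cost.
#' @param currency currency/base-year tag of the amounts, e.g. `"USD2017"`
#'   (analysis-ready) or `"TWD"` (needs [adjust_costs()] first).
#' @return `records` with a `costs` list column and attribute
#'   `cost_currency`.
#' @export
attach_costs <- function(records, cost_long, currency) {
  if (is.character(cost_long) && length(cost_long) == 1L)
    cost_long <- read.csv(cost_long, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "month", "cost") %in% names(cost_long)))
  if (any(cost_long$cost < 0)) stop("negative cost entries")
  if (missing(currency)) stop("'currency' must be stated explicitly")
  fu <- records$follow_up_months[match(cost_long$id, records$id)]
  if (anyNA(fu)) stop("cost table contains unknown patient ids")
  if (any(cost_long$month < 0 | cost_long$month >= pmax(fu, 1L)))
    stop("cost months outside the observed follow-up window")
  costs <- rep(list(numeric(0)), nrow(records))
  sp <- split(cost_long, cost_long$id)
  pos <- match(names(sp), as.character(records$id))
  for (k in seq_along(sp)) {
    i <- pos[k]
    v <- numeric(max(records$follow_up_months[i], 0L))
    v[sp[[k]]$month + 1L] <- sp[[k]]$cost
    costs[[i]] <- v
  }
  # patients with no cost rows still incur zero cost over follow-up
  none <- setdiff(seq_len(nrow(records)), pos)
  for (i in none) costs[[i]] <- numeric(records$follow_up_months[i])
  records$costs <- costs
  attr(records, "cost_currency") <- currency
  validate_records(records)
  records
}

#' Restrict a cohort to later diagnosis years
#'
#' Sensitivity-analysis filter keeping only patients diagnosed in or after
#' `min_dx_year`; record order is preserved.
#'
#' @param records patient records.
#' @param min_dx_year first diagnosis year to keep.
#' @return the subset (possibly empty), attributes preserved.
#' @export
restrict_cohort <- function(records, min_dx_year) {
  keep <- records$dx_year >= min_dx_year
  out <- records[keep, , drop = FALSE]
  attr(out, "cost_currency") <- attr(records, "cost_currency")
  out
}
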