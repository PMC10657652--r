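# National life tables and matched reference-cohort survival.
#
# A life table holds annual death probabilities q(sex, calendar year, age).
# Reference ("referent") individuals matched to each patient on sex, age and
# calendar year/month at diagnosis follow this mortality law; their pooled
# survival curve is the comparator against which loss of life expectancy is
# measured.

#' Construct a life table from a data frame
#'
#' @param df data frame with columns `sex` (`"F"`/`"M"`), `year` (calendar
#'   year), `age` (completed years, contiguous from 0 for every sex/year
#'   present) and `qx` (annual probability of death in `[0, 1]`).
#' @param terminal_age age at which death is certain; lookups at or beyond it
#'   return q = 1 regardless of table content. Default 110.
#' @return an object of class `"life_table"`.
#' @details Lookup policy at the edges: calendar years outside the table's
#'   range are clamped to the nearest available year (so projections beyond
#'   the last published year reuse that year); ages above the highest age in
#'   the table reuse the highest-age row; ages at or beyond `terminal_age`
#'   have q = 1, which guarantees that every survival curve reaches zero.
#' @export
as_life_table <- function(df, terminal_age = 110L) {
  need <- c("sex", "year", "age", "qx")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("life table is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (!all(df$sex %in% c("F", "M")))
    stop("life table 'sex' must be \"F\" or \"M\"; offending row(s): ",
         paste(head(which(!df$sex %in% c("F", "M")), 3L), collapse = ", "))
  if (!is_whole(df$year) || !is_whole(df$age) || any(df$age < 0))
    stop("life table 'year' and 'age' must be non-negative integers")
  bad_q <- which(!is.finite(df$qx) | df$qx < 0 | df$qx > 1)
  if (length(bad_q))
    stop("life table qx outside [0, 1] at row(s): ",
         paste(head(bad_q, 3L), collapse = ", "))
  key <- paste(df$sex, df$year, df$age)
  if (anyDuplicated(key))
    stop("duplicate life table key at row(s): ",
         paste(head(which(duplicated(key)), 3L), collapse = ", "))
  # contiguity: each (sex, year) block must cover ages 0..max(age) exactly
  sp <- split(df$age, paste(df$sex, df$year))
  for (nm in names(sp)) {
    a <- sort(sp[[nm]])
    if (a[1L] != 0L || !identical(as.integer(a), seq.int(0L, a[length(a)])))
      stop("ages not contiguous from 0 for (sex, year) = ", nm)
  }
  years <- sort(unique(df$year))
  ages <- 0:max(df$age)
  q <- array(NA_real_, dim = c(2L, length(years), length(ages)),
             dimnames = list(c("F", "M"), years, ages))
  q[cbind(match(df$sex, c("F", "M")), match(df$year, years), df$age + 1L)] <-
    df$qx
  structure(list(q = q, years = years, age_max = max(df$age),
                 terminal_age = as.integer(terminal_age)),
            class = "life_table")
}

#' Read a life table from CSV
#'
#' Expects a header `sex,year,age,qx`, one row per (sex, year, age); see
#' [as_life_table()] for validation and edge policy.
#'
#' @param path CSV file path.
#' @inheritParams as_life_table
#' @return a `"life_table"` object.
#' @export
load_life_table <- function(path, terminal_age = 110L) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(sex = "character"))
  as_life_table(df, terminal_age = terminal_age)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table: years %d-%d, ages 0-%d, terminal age %d>\n",
              min(x$years), max(x$years), x$age_max, x$terminal_age))
  invisible(x)
}

#' Annual death probability lookup (vectorised)
#'
#' Applies the edge policy: years clamp to the table range, ages above the
#' table's maximum reuse the oldest row, ages >= terminal age return 1.
#'
#' @param lt a `"life_table"`.
#' @param sex character vector of `"F"`/`"M"`.
#' @param year,age integer vectors (recycled to a common length).
#' @return numeric vector of annual death probabilities.
#' @export
lookup_q <- function(lt, sex, year, age) {
  n <- max(length(sex), length(year), length(age))
  sex <- rep_len(sex, n); year <- rep_len(year, n); age <- rep_len(age, n)
  si <- match(sex, c("F", "M"))
  if (anyNA(si)) stop("sex must be \"F\" or \"M\"")
  yi <- match(pmin(pmax(year, min(lt$years)), max(lt$years)), lt$years)
  if (anyNA(yi)) stop("life table has a gap in its calendar years")
  ai <- pmin(age, lt$age_max) + 1L
  q <- lt$q[cbind(si, yi, ai)]
  if (anyNA(q)) stop("life table has no entry for a requested (sex, year)")
  q[age >= lt$terminal_age] <- 1
  q
}

#' Monthly survival probability from an annual death probability
#'
#' Under a constant hazard within the year of age, the probability of
#' surviving one month is `(1 - q)^(1/12)`.
#'
#' @param q_annual annual probability of death in `[0, 1]`.
#' @return per-month survival probability.
#' @export
#' @examples
#' monthly_survival_prob(0.12)^12  # = 0.88
monthly_survival_prob <- function(q_annual) {
  if (any(q_annual < 0 | q_annual > 1, na.rm = TRUE))
    stop("q_annual must lie in [0, 1]")
  (1 - q_annual)^(1 / 12)
}

#' Referent profiles matched to a patient cohort
#'
#' One referent profile per patient, matched on sex, age, calendar year and
#' month at diagnosis.
#'
#' @param records a patient records data frame (see [read_patients()]).
#' @return data frame with columns `sex`, `age_at_index`, `index_year`,
#'   `index_month`.
#' @export
referent_profiles <- function(records) {
  stopifnot(nrow(records) > 0)
  data.frame(sex = records$sex, age_at_index = records$age_at_dx,
             index_year = records$dx_year, index_month = records$dx_month)
}

# Attained age and calendar year for month offsets 0..H-1.
# Age increments every 12 months after index; calendar year increments when
# the calendar month rolls past December (so a December index crosses the
# year boundary after one month).
# Returns the n x H matrix of annual q at each profile-month.
monthly_q_matrix <- function(profiles, lt, horizon_months) {
  H <- as.integer(horizon_months)
  n <- nrow(profiles)
  m <- 0:(H - 1L)
  age <- outer(profiles$age_at_index, m %/% 12L, `+`)
  yr <- (outer(profiles$index_month - 1L, m, `+`) %/% 12L) +
    profiles$index_year
  q <- lookup_q(lt, rep(profiles$sex, times = H), as.vector(yr),
                as.vector(age))
  matrix(q, nrow = n, ncol = H)
}

# Per-profile reference survival curves, deduplicated.
# Returns list(S = n_unique x (H+1) matrix of survival at months 0..H,
#              weight = counts, index = map from input rows to unique rows).
reference_survival_matrix <- function(profiles, lt, horizon_months,
                                      chunk = 2000L) {
  key <- paste(profiles$sex, profiles$age_at_index, profiles$index_year,
               profiles$index_month)
  idx <- match(key, unique(key))
  uni <- profiles[!duplicated(key), , drop = FALSE]
  H <- as.integer(horizon_months)
  S <- matrix(NA_real_, nrow = nrow(uni), ncol = H + 1L)
  for (st in seq(1L, nrow(uni), by = chunk)) {
    en <- min(st + chunk - 1L, nrow(uni))
    q <- monthly_q_matrix(uni[st:en, , drop = FALSE], lt, H)
    p <- (1 - q)^(1 / 12)
    S[st:en, ] <- cbind(1, t(apply(p, 1L, cumprod)))
  }
  list(S = S, weight = tabulate(idx, nbins = nrow(uni)), index = idx)
}

#' Exact expected survival of a matched reference cohort
#'
#' Computes the reference survival curve as the expectation over referents of
#' the product of monthly survival probabilities taken from the life table at
#' each referent's attained age and calendar year,
#' `S_ref(t) = (1/N) * sum_i prod_{m < t} p_i(m)`.
#' This is the exact counterpart of the Monte-Carlo construction in
#' [simulate_reference_cohort()] (its large-replicate limit).
#'
#' @param profiles referent profiles, see [referent_profiles()].
#' @param lt a `"life_table"`.
#' @param horizon_months length of the curve in months.
#' @return a `"reference"` [survival_curve()].
#' @export
expected_reference_survival <- function(profiles, lt, horizon_months) {
  if (is.null(nrow(profiles)) || nrow(profiles) == 0L)
    stop("empty profile list")
  rs <- reference_survival_matrix(profiles, lt, horizon_months)
  s <- drop(rs$weight %*% rs$S) / sum(rs$weight)
  survival_curve(0:horizon_months, s, type = "reference")
}

#' Monte-Carlo matched reference cohort
#'
#' Simulates `replicates_per_profile` referents for every profile. Each
#' referent's death month is drawn from the sequential monthly survival
#' probabilities implied by the life table (sampled by inverting the
#' cumulative survival product with one uniform draw, which is equivalent in
#' law to month-by-month Bernoulli thinning). Referents are pooled as
#' individuals and the empirical survival curve returned; there is no
#' censoring. The same seed reproduces the curve exactly.
#'
#' @inheritParams expected_reference_survival
#' @param replicates_per_profile number of simulated referents per profile
#'   (>= 1). Default 100.
#' @param seed integer seed (required, for reproducibility).
#' @return a `"reference"` [survival_curve()].
#' @export
simulate_reference_cohort <- function(profiles, lt, horizon_months,
                                      replicates_per_profile = 100L,
                                      seed) {
  if (is.null(nrow(profiles)) || nrow(profiles) == 0L)
    stop("empty profile list")
  stopifnot(replicates_per_profile >= 1L)
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  rs <- reference_survival_matrix(profiles, lt, horizon_months)
  alive <- numeric(horizon_months + 1L)
  total <- 0L
  for (i in seq_len(nrow(rs$S))) {
    nrep <- replicates_per_profile * rs$weight[i]
    u <- sort(runif(nrep))
    # referent alive at month t iff its uniform <= S_i(t)
    alive <- alive + findInterval(rs$S[i, ], u)
    total <- total + nrep
  }
  survival_curve(0:horizon_months, alive / total, type = "reference")
}
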