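# Synthetic registry generator. Emulates the statistical structure of a
# national-insurance diagnosis registry — staggered diagnosis years, an
# age/sex mix typical of an adult-onset chronic disease, administrative
# censoring at a fixed calendar date, group-specific proportional excess
# mortality on top of a national life table, and right-skewed monthly costs
# with end-of-life escalation — with every quantity's ground truth known, so
# the estimation pipeline can be validated without restricted data.
#
# The excess hazard is additive on the reference hazard with a multiplicative
# group factor (the relative-survival convention), which is exactly the
# estimand the extrapolation method targets.

#' Define a synthetic registry scenario
#'
#' Defaults describe the registered default scenario used throughout the
#' package's validation: a Gompertz life table calibrated to modern
#' high-income mortality, a 10,000-patient cohort resembling an adult
#' autoimmune-disease registry (diagnoses staggered over 1999-2017,
#' administrative censoring at December 2017), a baseline excess hazard of
#' 7e-4/month with a 1.38 hazard ratio for the depression groups at 3.8%
#' prevalence, and Gamma-distributed monthly costs (mean 280 2017-USD,
#' coefficient of variation 1) tripled over the final six months of life.
#'
#' @param n cohort size.
#' @param age_mean,age_sd,age_range age-at-diagnosis distribution: normal,
#'   rounded to whole years, truncated to `age_range`.
#' @param p_male probability of male sex.
#' @param dx_years inclusive range of diagnosis calendar years (uniform).
#' @param admin_censor `c(year, month)` of administrative censoring.
#' @param gompertz_a,gompertz_b Gompertz baseline hazard (per year) and slope
#'   (per year of age) of the reference mortality law.
#' @param sex_mult named multipliers on the baseline hazard for `F` and `M`.
#' @param calendar_drift log-linear mortality improvement per calendar year
#'   (negative = improving), applied relative to `drift_ref_year`.
#' @param drift_ref_year anchor year of the calendar drift.
#' @param excess0 baseline excess hazard, per month, added to the reference
#'   monthly hazard for every patient.
#' @param group_hr named multipliers on the excess hazard by depression
#'   group (`none`, `major`, `minor`).
#' @param p_depression prevalence of depression at diagnosis.
#' @param p_major share of depression that is major (the remainder minor).
#' @param cost_base mean monthly cost at age 50, analysis currency.
#' @param cost_age_slope relative increase in mean cost per year of attained
#'   age beyond 50.
#' @param eol_mult multiplier on mean cost during the final `eol_months`
#'   months before (true) death.
#' @param eol_months length of the end-of-life escalation window.
#' @param cost_cv coefficient of variation of the Gamma cost noise
#'   (0 = deterministic).
#' @param truth_discount annual discount rate used for the ground-truth
#'   lifetime cost stored in the truth sidecar.
#' @return list of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(n = 10000L,
                               age_mean = 53, age_sd = 14,
                               age_range = c(16L, 95L),
                               p_male = 0.235,
                               dx_years = c(1999L, 2017L),
                               admin_censor = c(2017L, 12L),
                               gompertz_a = 3.5e-5, gompertz_b = 0.09,
                               sex_mult = c(F = 0.8, M = 1.4),
                               calendar_drift = -0.01,
                               drift_ref_year = 2008L,
                               excess0 = 7e-4,
                               group_hr = c(none = 1, major = 1.38,
                                            minor = 1.38),
                               p_depression = 0.038, p_major = 0.30,
                               cost_base = 280, cost_age_slope = 0.005,
                               eol_mult = 3, eol_months = 6L,
                               cost_cv = 1,
                               truth_discount = 0.03) {
  stopifnot(n >= 1L, gompertz_a >= 0, gompertz_b >= 0, all(sex_mult > 0),
            excess0 >= 0, all(group_hr > 0), p_depression >= 0,
            p_depression <= 1, p_major >= 0, p_major <= 1, cost_base >= 0,
            eol_mult >= 1, eol_months >= 0, cost_cv >= 0)
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' Gompertz life table of a synthetic scenario
#'
#' Annual death probabilities
#' `q(sex, year, age) = 1 - exp(-a * m_sex * d_year * exp(b * age))` with
#' `d_year = exp(drift * (year - drift_ref_year))`, for ages 0..110 (q = 1 at
#' the terminal age 110) and the scenario's calendar-year span.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a `"life_table"`.
#' @export
make_life_table <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  years <- scenario$dx_years[1L]:scenario$admin_censor[1L]
  ages <- 0:110
  grid <- expand.grid(sex = c("F", "M"), year = years, age = ages,
                      stringsAsFactors = FALSE)
  m <- scenario$sex_mult[grid$sex]
  d <- exp(scenario$calendar_drift * (grid$year - scenario$drift_ref_year))
  q <- 1 - exp(-scenario$gompertz_a * m * d * exp(scenario$gompertz_b *
                                                    grid$age))
  q <- pmin(pmax(q, 0), 1)
  q[grid$age == 110L] <- 1
  as_life_table(data.frame(sex = grid$sex, year = grid$year, age = grid$age,
                           qx = q),
                terminal_age = 110L)
}

# mean monthly cost at month offset t for a patient aged age0 at index
cost_mean_at <- function(scenario, age0, t) {
  pmax(scenario$cost_base *
         (1 + scenario$cost_age_slope * (age0 + t / 12 - 50)),
       0.05 * scenario$cost_base)
}

#' Draw a synthetic patient cohort with known ground truth
#'
#' Each patient's monthly death probability is
#' `1 - exp(-(h_ref(m) + excess0 * HR(group)))`, where `h_ref(m)` is the
#' reference monthly hazard from the scenario's life table at the patient's
#' attained age and calendar year. Death months are drawn by inverting the
#' cumulative survival product (equivalent in law to month-by-month
#' Bernoulli draws); follow-up is truncated by administrative censoring at
#' the scenario's cutoff date. Depression labels are assigned by prevalence.
#'
#' The returned `truth` sidecar holds, per patient, the uncensored death
#' month, the exact (quadrature) life expectancy under the patient's own
#' hazard and under the reference law, and the exact expected discounted
#' lifetime cost under the scenario's cost law — quantities the estimation
#' pipeline never sees.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed integer seed (required).
#' @return list with `records` (patient data frame), `truth` (sidecar data
#'   frame with `id`, `death_month`, `le`, `ref_le`, `lifetime_cost`), and
#'   `life_table`.
#' @export
draw_cohort <- function(scenario, seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  n <- scenario$n
  # demographics: truncated-normal ages, staggered diagnosis dates
  age <- round(rnorm(n, scenario$age_mean, scenario$age_sd))
  while (any(bad <- age < scenario$age_range[1L] |
               age > scenario$age_range[2L]))
    age[bad] <- round(rnorm(sum(bad), scenario$age_mean, scenario$age_sd))
  sex <- ifelse(runif(n) < scenario$p_male, "M", "F")
  dx_year <- scenario$dx_years[1L] +
    sample.int(scenario$dx_years[2L] - scenario$dx_years[1L] + 1L, n,
               replace = TRUE) - 1L
  dx_month <- sample.int(12L, n, replace = TRUE)
  dep <- ifelse(runif(n) < scenario$p_depression,
                ifelse(runif(n) < scenario$p_major, "major", "minor"),
                "none")
  hr <- unname(scenario$group_hr[dep])
  lt <- make_life_table(scenario)
  # +12: include the terminal q = 1 year so every survival path reaches 0
  H <- max((110L - age) * 12L) + 12L
  u <- runif(n)  # death-month inversion draws
  admin <- (scenario$admin_censor[1L] - dx_year) * 12L +
    (scenario$admin_censor[2L] - dx_month)
  death <- integer(n); le <- numeric(n); ref_le <- numeric(n)
  cost_true <- numeric(n)
  prof <- data.frame(sex = sex, age_at_index = age, index_year = dx_year,
                     index_month = dx_month)
  k <- scenario$eol_months
  disc <- (1 + scenario$truth_discount)^(-(0:(H - 1L)) / 12)
  for (st in seq(1L, n, by = 2000L)) {
    en <- min(st + 1999L, n)
    blk <- st:en
    q <- monthly_q_matrix(prof[blk, , drop = FALSE], lt, H)
    h_ref <- -log(pmax(1 - q, 0)) / 12          # Inf where q = 1
    p_all <- exp(-(h_ref + scenario$excess0 * hr[blk]))
    S <- cbind(1, t(apply(p_all, 1L, cumprod))) # months 0..H
    S_ref <- cbind(1, t(apply(exp(-h_ref), 1L, cumprod)))
    # death month: first t with S(t) < u (S nonincreasing, S(H) = 0)
    death[blk] <- max.col(S < u[blk], ties.method = "first") - 1L
    le[blk] <- (rowSums(S) - (1 + S[, H + 1L]) / 2) / 12
    ref_le[blk] <- (rowSums(S_ref) - (1 + S_ref[, H + 1L]) / 2) / 12
    # exact expected discounted lifetime cost:
    # E[c(t) 1(alive at t)] = S(t) mu(t) (1 + (mult-1) P(die within k | alive))
    St <- S[, seq_len(H), drop = FALSE]
    Sk <- cbind(S, matrix(0, nrow(S), k))[, seq_len(H) + k, drop = FALSE]
    p_eol <- ifelse(St > 0, 1 - Sk / St, 0)
    mu <- outer(age[blk], 0:(H - 1L),
                function(a, t) cost_mean_at(scenario, a, t))
    contrib <- St * mu * (1 + (scenario$eol_mult - 1) * p_eol)
    cost_true[blk] <- contrib %*% disc
  }
  event <- as.integer(death <= admin)
  fu <- pmin(death, pmax(admin, 0L))
  records <- data.frame(id = seq_len(n), sex = sex, age_at_dx = age,
                        dx_year = dx_year, dx_month = dx_month,
                        follow_up_months = fu, event = event,
                        depression = dep, stringsAsFactors = FALSE)
  validate_records(records)
  truth <- data.frame(id = seq_len(n), death_month = death, le = le,
                      ref_le = ref_le, lifetime_cost = cost_true)
  list(records = records, truth = truth, life_table = lt)
}

#' Draw monthly cost vectors for a synthetic cohort
#'
#' Monthly costs are Gamma-distributed with mean
#' `cost_base * (1 + cost_age_slope * (age - 50))` at the attained age,
#' multiplied by `eol_mult` during the final `eol_months` months before the
#' patient's true death month (escalation keyed to the true death, so a
#' patient censored shortly before death already shows rising costs). Costs
#' are emitted only for observed months (`0 .. follow_up - 1`): nothing
#' leaks past censoring. Costs are tagged `"USD2017"`.
#'
#' @param cohort list from [draw_cohort()] (uses `records` and the truth
#'   sidecar's death months for the escalation window only).
#' @param scenario the same [synthetic_scenario()].
#' @param seed integer seed (required).
#' @return the `records` data frame with a `costs` list column.
#' @export
draw_costs <- function(cohort, scenario, seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  records <- cohort$records
  death <- cohort$truth$death_month[match(records$id, cohort$truth$id)]
  cv <- scenario$cost_cv
  shape <- if (cv > 0) 1 / cv^2 else Inf
  costs <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    f <- records$follow_up_months[i]
    if (f == 0L) { costs[[i]] <- numeric(0); next }
    t <- 0:(f - 1L)
    mu <- cost_mean_at(scenario, records$age_at_dx[i], t)
    mu <- mu * ifelse(t >= death[i] - scenario$eol_months,
                      scenario$eol_mult, 1)
    costs[[i]] <- if (cv > 0) rgamma(f, shape = shape, rate = shape / mu)
                  else mu
  }
  records$costs <- costs
  attr(records, "cost_currency") <- "USD2017"
  validate_records(records)
  records
}

#' Generate a complete synthetic registry
#'
#' Convenience wrapper: [draw_cohort()] then [draw_costs()].
#'
#' @inheritParams draw_cohort
#' @return list with `records` (including costs), `truth`, `life_table`.
#' @export
draw_registry <- function(scenario, seed) {
  cohort <- draw_cohort(scenario, seed = seed)
  cohort$records <- draw_costs(cohort, scenario, seed = seed + 1L)
  cohort
}

#' Write a synthetic registry to CSV files
#'
#' Emits the patient table, long-format cost matrix, life table and truth
#' sidecar in the package's CSV schemas.
#'
#' @param cohort list from [draw_registry()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_registry <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             costs = file.path(dir, "costs.csv"),
             life_table = file.path(dir, "life_table.csv"),
             truth = file.path(dir, "truth.csv"))
  recs <- cohort$records
  write.csv(recs[setdiff(names(recs), "costs")], paths["patients"],
            row.names = FALSE)
  if (!is.null(recs$costs)) {
    long <- do.call(rbind, lapply(seq_len(nrow(recs)), function(i) {
      v <- recs$costs[[i]]
      if (!length(v)) return(NULL)
      data.frame(id = recs$id[i], month = seq_along(v) - 1L, cost = v)
    }))
    write.csv(long, paths["costs"], row.names = FALSE)
  }
  lt <- cohort$life_table
  grid <- expand.grid(sex = c("F", "M"), year = lt$years, age = 0:lt$age_max,
                      stringsAsFactors = FALSE)
  grid$qx <- lookup_q(lt, grid$sex, grid$year, grid$age)
  write.csv(grid, paths["life_table"], row.names = FALSE)
  write.csv(cohort$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
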