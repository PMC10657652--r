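# fixtures built in code: toy life tables and miniature cohorts

# constant-q life table covering both sexes, ages 0..110
flat_life_table <- function(q = 0.12, years = 2000:2017, qM = q) {
  grid <- expand.grid(sex = c("F", "M"), year = years, age = 0:110,
                      stringsAsFactors = FALSE)
  grid$qx <- ifelse(grid$sex == "F", q, qM)
  as_life_table(grid)
}

# Gompertz toy table with unit sex multipliers and no calendar drift
gompertz_life_table <- function(a = 3.5e-5, b = 0.09, years = 2000:2017) {
  grid <- expand.grid(sex = c("F", "M"), year = years, age = 0:110,
                      stringsAsFactors = FALSE)
  grid$qx <- pmin(1, 1 - exp(-a * exp(b * grid$age)))
  grid$qx[grid$age == 110] <- 1
  as_life_table(grid)
}

# minimal patient records; vectors recycled to a common length
make_records <- function(follow_up, event, sex = "F", age = 60L,
                         dx_year = 2005L, dx_month = 1L,
                         depression = "none") {
  n <- max(length(follow_up), length(event))
  data.frame(id = seq_len(n), sex = rep_len(sex, n),
             age_at_dx = rep_len(age, n), dx_year = rep_len(dx_year, n),
             dx_month = rep_len(dx_month, n),
             follow_up_months = rep_len(follow_up, n),
             event = rep_len(event, n),
             depression = rep_len(depression, n),
             stringsAsFactors = FALSE)
}

# attach a list of cost vectors with the analysis currency tag
with_costs <- function(records, costs, currency = "USD2017") {
  records$costs <- costs
  attr(records, "cost_currency") <- currency
  records
}

# bare cost curve on months 0..(length(cost)-1)
make_cost_curve <- function(cost, n_contributing = rep(1L, length(cost)),
                            currency = "USD2017") {
  out <- data.frame(month = seq_along(cost) - 1L, cost = cost,
                    n_contributing = n_contributing)
  class(out) <- c("cost_curve", "data.frame")
  attr(out, "currency") <- currency
  out
}
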