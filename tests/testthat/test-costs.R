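test_that("mean monthly cost averages over surviving contributors", {
  rec <- with_costs(make_records(follow_up = c(1, 1), event = 0),
                    list(10, 30))
  cc <- mean_monthly_cost(rec)
  expect_equal(cc$cost, 20)

  # a patient censored at month 3 contributes to months 0-2 only
  rec2 <- with_costs(make_records(follow_up = c(3, 6), event = 0),
                     list(rep(12, 3), rep(24, 6)))
  cc2 <- mean_monthly_cost(rec2)
  expect_equal(cc2$n_contributing, c(2L, 2L, 2L, 1L, 1L, 1L))
  expect_equal(cc2$cost, c(18, 18, 18, 24, 24, 24))

  expect_error(mean_monthly_cost(with_costs(make_records(2, 0),
                                            list(c(-1, 2)))), "negative")
})

test_that("sample means of i.i.d. costs concentrate at their expectation", {
  set.seed(31)
  n <- 800L
  fu <- sample(6:24, n, replace = TRUE)
  rec <- with_costs(make_records(fu, event = 0),
                    lapply(fu, function(f) rgamma(f, shape = 4, rate = 0.04)))
  cc <- mean_monthly_cost(rec)
  se <- sqrt(100^2 / 4) / sqrt(cc$n_contributing)  # gamma sd = mean/sqrt(shape)
  expect_true(all(abs(cc$cost - 100) < 3 * se))
})

test_that("CPI adjustment converts nominal TWD to base-year USD", {
  cpi <- cpi_series(data.frame(year = 2015:2017, index = c(95, 98, 100)))
  expect_equal(cpi_adjust(3044, 2017, cpi), 100)
  expect_equal(cpi_adjust(95, 2015, cpi), 100 / 30.44, tolerance = 1e-9)
  expect_equal(cpi_adjust(0, 2016, cpi), 0)
  expect_error(cpi_adjust(10, 1999, cpi), "missing year")
  expect_error(cpi_series(data.frame(year = 2000, index = 1)), "base year")
})

test_that("cohort costs must be CPI-adjusted before estimation", {
  rec <- with_costs(make_records(follow_up = c(14, 14), event = 0,
                                 dx_year = 2016L, dx_month = 11L),
                    list(rep(3044, 14), rep(3044, 14)), currency = "TWD")
  expect_error(mean_monthly_cost(rec), "CPI-adjust")
  cpi <- cpi_series(data.frame(year = 2016:2017, index = c(100, 100)))
  adj <- adjust_costs(rec, cpi)
  expect_identical(attr(adj, "cost_currency"), "USD2017")
  expect_equal(mean_monthly_cost(adj)$cost, rep(100, 14))
  expect_error(adjust_costs(adj, cpi), "TWD")
})

test_that("trailing smoothing weights by contributors and carries forward", {
  cc <- make_cost_curve(c(10, 20, 30))
  sm <- smooth_and_extend_cost(cc, window_months = 2L, horizon_months = 6L)
  # the tail carries the last smoothed value (25), not the last raw value
  expect_equal(sm$cost, c(10, 15, 25, 25, 25, 25, 25))
  expect_equal(sm$source, c(rep("observed", 3), rep("extrapolated", 4)))

  # precision weighting: month with more contributors dominates the window
  ccw <- make_cost_curve(c(10, 40), n_contributing = c(3L, 1L))
  expect_equal(smooth_and_extend_cost(ccw, 2L, 1L)$cost[2],
               (3 * 10 + 1 * 40) / 4)

  # constant curve is invariant, including the extrapolated tail
  ccc <- make_cost_curve(rep(7, 24))
  expect_true(all(smooth_and_extend_cost(ccc, 12L, 60L)$cost == 7))

  expect_error(smooth_and_extend_cost(make_cost_curve(1:3), 12L, 20L),
               "window larger")
})

test_that("lifetime cost reduces to closed forms", {
  # rectangle: survive exactly 120 months at cost 100, undiscounted
  surv <- data.frame(month = 0:120, survival = c(rep(1, 120), 0))
  cost <- make_cost_curve(rep(100, 121))
  lc <- lifetime_cost(surv, cost, discount_rate = 0)
  expect_equal(lc$lifetime_cost, 12000)

  # zero cost
  expect_equal(lifetime_cost(surv, make_cost_curve(rep(0, 121)), 0.03)$
                 lifetime_cost, 0)

  # exponential survival, constant cost, 3%/yr: geometric series oracle
  mu <- 0.01; H <- 600L; c0 <- 250; r <- 0.03
  surv2 <- data.frame(month = 0:H, survival = exp(-mu * (0:H)))
  lc2 <- lifetime_cost(surv2, make_cost_curve(rep(c0, H + 1)), r)
  rho <- exp(-mu) * (1 + r)^(-1 / 12)
  oracle <- c0 * (1 - rho^(H + 1)) / (1 - rho)
  expect_equal(lc2$lifetime_cost, oracle, tolerance = 1e-6)

  expect_error(lifetime_cost(surv, make_cost_curve(rep(1, 60)), 0.03),
               "grid mismatch")
})

test_that("undiscounted lifetime cost of a constant profile tracks 12*LE*c", {
  surv <- data.frame(month = 0:240, survival = exp(-0.008 * (0:240)))
  lc <- lifetime_cost(surv, make_cost_curve(rep(50, 241)), 0)
  # rectangle sum vs trapezoid differ by exactly c*(S(0) + S(end))/2
  expect_equal(lc$lifetime_cost - 12 * lc$LE * 50,
               50 * (1 + exp(-0.008 * 240)) / 2, tolerance = 1e-9)
})

test_that("lifetime cost is monotone in discount rate and in survival", {
  surv_hi <- data.frame(month = 0:300, survival = exp(-0.005 * (0:300)))
  surv_lo <- data.frame(month = 0:300, survival = exp(-0.009 * (0:300)))
  cost <- make_cost_curve(rep(100, 301))
  v <- vapply(c(0, 0.03, 0.05),
              function(r) lifetime_cost(surv_hi, cost, r)$lifetime_cost,
              numeric(1))
  expect_true(all(diff(v) < 0))
  expect_gt(lifetime_cost(surv_hi, cost, 0.03)$lifetime_cost,
            lifetime_cost(surv_lo, cost, 0.03)$lifetime_cost)
})
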