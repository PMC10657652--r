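test_that("logit relative survival handles identity, half and decay ratios", {
  lt <- gompertz_life_table()
  prof <- data.frame(sex = "F", age_at_index = 53L, index_year = 2005L,
                     index_month = 1L)
  ref <- expected_reference_survival(prof, lt, 120L)

  # identical cohorts sit on the clipped plateau
  km_same <- survival_curve(0:120, ref$survival, type = "observed")
  w <- logit_relative_survival(km_same, ref)
  expect_true(all(abs(w$W - qlogis(1 - 1e-6)) < 1e-9))

  # ratio one half gives logit zero
  s_half <- ref$survival * c(1, rep(0.5, 120))
  w2 <- logit_relative_survival(survival_curve(0:120, s_half,
                                               type = "observed"), ref)
  expect_equal(w2$W[-1], rep(0, 120), tolerance = 1e-12)

  # exponential excess decay, closed form at t = 60
  lam <- 0.01
  s_exp <- ref$survival * exp(-lam * (0:120))
  w3 <- logit_relative_survival(survival_curve(0:120, s_exp,
                                               type = "observed"), ref)
  expect_equal(w3$W[61], log(exp(-0.6) / (1 - exp(-0.6))), tolerance = 1e-9)

  short_ref <- survival_curve(0:60, ref$survival[1:61], type = "reference")
  expect_error(logit_relative_survival(km_same, short_ref), "grid mismatch")
})

test_that("extrapolating a cohort on the reference law recovers it exactly", {
  lt <- gompertz_life_table()
  prof <- data.frame(sex = "F", age_at_index = 60L, index_year = 2005L,
                     index_month = 1L)
  H <- (110L - 60L) * 12L
  ref <- expected_reference_survival(prof, lt, H)
  km <- survival_curve(0:180, ref$survival[1:181], type = "observed")
  ex <- rolling_extrapolate(km, ref)
  # no excess mortality: loss of LE collapses to the clipping epsilon scale
  expect_lt(abs(ex$loss_of_LE), 1e-3)
  expect_equal(ex$LE_ref - ex$LE, ex$loss_of_LE)  # conservation, exact
})

test_that("constant excess hazard is recovered against quadrature truth", {
  lt <- gompertz_life_table()
  prof <- data.frame(sex = "F", age_at_index = 53L, index_year = 2005L,
                     index_month = 1L)
  H <- (110L - 53L) * 12L
  ref <- expected_reference_survival(prof, lt, H)
  for (lam in c(0.005, 0.01, 0.02)) {
    s_obs <- exp(-lam * (0:180)) * ref$survival[1:181]
    km <- survival_curve(0:180, s_obs, type = "observed")
    ex <- rolling_extrapolate(km, ref)
    truth <- (sum(exp(-lam * (0:H)) * ref$survival) - 1 / 2) / 12
    expect_lt(abs(ex$LE - truth) / truth, 0.05)
    expect_true(all(diff(ex$curve$survival) <= 1e-12))
    expect_equal(ex$LE_ref - ex$LE, ex$loss_of_LE)
  }
})

test_that("a cohort dying immediately yields LE of half a month", {
  lt <- gompertz_life_table()
  prof <- data.frame(sex = "F", age_at_index = 80L, index_year = 2005L,
                     index_month = 1L)
  H <- (110L - 80L) * 12L
  ref <- expected_reference_survival(prof, lt, H)
  km <- survival_curve(0:30, c(1, rep(0, 30)), type = "observed")
  ex <- rolling_extrapolate(km, ref)
  expect_equal(ex$LE, 1 / 24, tolerance = 1e-3)
  expect_equal(ex$loss_of_LE, ex$LE_ref - 1 / 24, tolerance = 1e-3)
})

test_that("the first rolling step equals an explicit spline refit", {
  lt <- gompertz_life_table()
  prof <- data.frame(sex = "F", age_at_index = 60L, index_year = 2005L,
                     index_month = 1L)
  H <- (110L - 60L) * 12L
  ref <- expected_reference_survival(prof, lt, H)
  s_obs <- exp(-0.004 * (0:72)) * ref$survival[1:73]
  km <- survival_curve(0:72, s_obs, type = "observed")
  ex <- rolling_extrapolate(km, ref, weighting = "equal", min_at_risk = 0L)
  # oracle: one unweighted spline fit on the log-ratio series, predict t+1
  series <- data.frame(month = 0:72, W = log(s_obs / ref$survival[1:73]))
  pred <- predict(fit_rcs(series, 3), 73)
  expect_equal(ex$curve$survival[74],
               min(min(exp(pred), 1) * ref$survival[74],
                   ex$curve$survival[73]),
               tolerance = 1e-9)
})

test_that("stopping honours the reference threshold and input contracts", {
  lt <- gompertz_life_table()
  prof <- data.frame(sex = "F", age_at_index = 60L, index_year = 2005L,
                     index_month = 1L)
  H <- (110L - 60L) * 12L + 12L  # terminal q = 1 year forces S_ref to zero
  ref <- expected_reference_survival(prof, lt, H)
  km <- survival_curve(0:48, ref$survival[1:49] * exp(-0.002 * 0:48),
                       type = "observed")
  ex <- rolling_extrapolate(km, ref)
  expect_identical(ex$stop_reason, "ref_below_eps")
  expect_lt(ref$survival[ex$stop_month + 2], 1e-4)
  expect_gte(ref$survival[ex$stop_month + 1], 1e-4)

  expect_error(rolling_extrapolate(
    survival_curve(0:10, rep(1, 11), type = "observed"), ref), "24 months")
  expect_error(rolling_extrapolate(
    km, survival_curve(0:30, ref$survival[1:31], type = "reference")),
    "too short")
})

test_that("z-test matches closed forms and the published worked example", {
  expect_equal(z_test(3, 1, 3, 2), list(z = 0, p = 1))
  se <- sqrt(1.2^2 + 0.9^2)
  zt <- z_test(5 + 1.96 * se, 1.2, 5, 0.9)
  expect_equal(zt$p, 2 * pnorm(-1.96), tolerance = 1e-12)
  # loss-of-LE contrast: 5.60 (1.85) vs 4.76 (0.60)
  zt2 <- z_test(5.60, 1.85, 4.76, 0.60)
  expect_equal(zt2$z, 0.84 / sqrt(1.85^2 + 0.60^2), tolerance = 1e-12)
  expect_equal(zt2$p, 0.667, tolerance = 0.002)
  expect_error(z_test(1, 0, 2, 1), "positive")
})
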