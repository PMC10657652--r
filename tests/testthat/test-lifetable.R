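test_that("life table CSV round-trips and validates its schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sex = "F", year = 2010, age = 0:2, qx = 0.1), path,
            row.names = FALSE)
  lt <- load_life_table(path)
  expect_s3_class(lt, "life_table")
  expect_equal(lookup_q(lt, "F", 2010L, 0:2), rep(0.1, 3))

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sex = "F", year = 2010, age = 0:2,
                       qx = c(0.1, 1.2, 0.1)), bad, row.names = FALSE)
  expect_error(load_life_table(bad), "qx outside")

  expect_error(as_life_table(data.frame(sex = "F", year = 2010,
                                        age = c(0, 2), qx = 0.1)),
               "contiguous")
  expect_error(as_life_table(data.frame(sex = "F", year = 2010,
                                        age = c(0, 1, 1), qx = 0.1)),
               "duplicate")
  expect_error(as_life_table(data.frame(sex = "F", year = 2010, age = 0,
                                        qx = 0.1)[, -4]), "missing column")
})

test_that("lookups clamp calendar years and apply the terminal-age rule", {
  lt <- flat_life_table(q = 0.12)
  # beyond the last table year falls back to the last year
  expect_identical(lookup_q(lt, "F", 2030L, 60L),
                   lookup_q(lt, "F", 2017L, 60L))
  expect_identical(lookup_q(lt, "M", 1980L, 60L),
                   lookup_q(lt, "M", 2000L, 60L))
  # at and beyond the terminal age death is certain
  expect_equal(lookup_q(lt, "F", 2010L, c(110L, 150L)), c(1, 1))
})

test_that("monthly survival probability matches the constant-hazard form", {
  expect_equal(monthly_survival_prob(0), 1)
  expect_equal(monthly_survival_prob(1), 0)
  # independent 12-fold product check
  expect_equal(monthly_survival_prob(0.12)^12, 0.88, tolerance = 1e-12)
  expect_error(monthly_survival_prob(1.2), "\\[0, 1\\]")
})

test_that("expected reference survival multiplies monthly probabilities", {
  lt <- flat_life_table(q = 0.12)
  prof <- data.frame(sex = "F", age_at_index = 60L, index_year = 2010L,
                     index_month = 1L)
  s <- expected_reference_survival(prof, lt, 24L)
  expect_equal(s$survival[13], 0.88, tolerance = 1e-12)
  expect_equal(s$survival[25], 0.88^2, tolerance = 1e-12)

  # immortal table
  s0 <- expected_reference_survival(prof, flat_life_table(q = 0), 24L)
  expect_true(all(s0$survival == 1))

  # averaging over an immortal and an immediately-dying referent
  lt2 <- flat_life_table(q = 0, qM = 1)
  prof2 <- data.frame(sex = c("F", "M"), age_at_index = 60L,
                      index_year = 2010L, index_month = 1L)
  s2 <- expected_reference_survival(prof2, lt2, 24L)
  expect_equal(s2$survival[-1], rep(0.5, 24))

  expect_error(expected_reference_survival(prof[0, ], lt, 12L), "empty")
})

test_that("calendar-year bookkeeping rolls over after December", {
  # different q in consecutive years, constant across ages
  grid <- expand.grid(sex = "F", year = 2005:2006, age = 0:110,
                      stringsAsFactors = FALSE)
  grid$qx <- ifelse(grid$year == 2005, 0.1, 0.3)
  lt <- as_life_table(grid)
  prof <- data.frame(sex = "F", age_at_index = 30L, index_year = 2005L,
                     index_month = 12L)
  s <- expected_reference_survival(prof, lt, 2L)
  expect_equal(s$survival[2], 0.9^(1 / 12), tolerance = 1e-12)  # Dec 2005
  expect_equal(s$survival[3], 0.9^(1 / 12) * 0.7^(1 / 12),
               tolerance = 1e-12)                               # Jan 2006
})

test_that("any 12 consecutive months carry the annual death mass", {
  # property: under a homogeneous table S(t+12)/S(t) = 1 - q
  set.seed(7)
  for (rep in 1:20) {
    q <- runif(1, 0.01, 0.6)
    lt <- flat_life_table(q = q)
    prof <- data.frame(sex = "F", age_at_index = sample(20:80, 1),
                       index_year = sample(2001:2016, 1),
                       index_month = sample(1:12, 1))
    s <- expected_reference_survival(prof, lt, 48L)$survival
    for (t0 in c(0L, 7L, 24L))
      expect_equal(s[t0 + 13] / s[t0 + 1], 1 - q, tolerance = 1e-10)
  }
})

test_that("Monte-Carlo referents converge to and reproduce the expectation", {
  lt <- flat_life_table(q = 0.12)
  prof <- data.frame(sex = "F", age_at_index = 60L, index_year = 2010L,
                     index_month = 1L)
  mc <- simulate_reference_cohort(prof, lt, 24L,
                                  replicates_per_profile = 10000L, seed = 3)
  # binomial MC error bound at 10,000 replicates
  expect_lt(abs(mc$survival[13] - 0.88), 3 * sqrt(0.88 * 0.12 / 10000))
  mc2 <- simulate_reference_cohort(prof, lt, 24L,
                                   replicates_per_profile = 10000L, seed = 3)
  expect_identical(mc$survival, mc2$survival)

  # certain death at the index age kills every replicate within a year
  lt1 <- flat_life_table(q = 1)
  mc1 <- simulate_reference_cohort(prof, lt1, 12L,
                                   replicates_per_profile = 50L, seed = 1)
  expect_equal(mc1$survival[13], 0)
  expect_error(simulate_reference_cohort(prof, lt, 12L,
                                         replicates_per_profile = 10L),
               "seed")
})

test_that("reference curves are monotone and start at one", {
  lt <- gompertz_life_table()
  prof <- data.frame(sex = c("F", "M"), age_at_index = c(40L, 70L),
                     index_year = 2005L, index_month = c(6L, 12L))
  for (s in list(expected_reference_survival(prof, lt, 300L),
                 simulate_reference_cohort(prof, lt, 300L, 200L, seed = 5))) {
    expect_equal(s$survival[1], 1)
    expect_true(all(diff(s$survival) <= 1e-12))
    expect_true(all(s$survival >= 0 & s$survival <= 1))
  }
})
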