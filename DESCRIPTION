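Package: lexcost
Title: Life Expectancy Loss and Lifetime Healthcare Cost from Registry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates life expectancy after diagnosis, loss of life expectancy
    against a demographically matched general-population reference, and
    survival-weighted discounted lifetime healthcare cost for registry cohorts
    followed over a limited window. Reference cohorts are built from national
    life tables matched on sex, age and calendar year at diagnosis, by exact
    expectation or Monte-Carlo simulation. Survival beyond follow-up is
    extrapolated with a rolling restricted-cubic-spline model of the logit
    relative survival ratio. Includes monthly-grid Kaplan-Meier estimation,
    CPI adjustment of costs, patient-level bootstrap uncertainty, z-tests for
    group contrasts, and a synthetic registry generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    splines,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
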