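# lexcost

Life expectancy, loss of life expectancy, and lifetime healthcare cost for
diagnosis cohorts followed in national registries.

Registry cohorts are observed for a limited window — follow-up ends at a
fixed administrative censoring date — but disease-burden questions are
lifetime questions. `lexcost` estimates, for a cohort of newly diagnosed
patients and any stratification of it:

* **LE** — life expectancy after diagnosis, the area under the cohort's
  survival curve extrapolated to a lifetime horizon;
* **loss-of-LE** — the area between that curve and the survival of a
  reference cohort matched on sex, age, and calendar year at diagnosis,
  built from a national life table;
* **lifetime healthcare cost** — the survival-weighted, discounted sum of
  mean monthly costs among survivors, in 2017 USD, and its cost per
  life-year.

The survival extrapolation follows the semiparametric relative-survival
approach: the transformed relative survival ratio
`S_cohort(t) / S_ref(t)` — fitted on the log scale by default, where it is
exactly linear in time under a constant excess hazard, with the classical
logit scale available as an option — is modelled by a restricted cubic
spline over a sliding window that predicts it one month ahead; each
prediction is appended, the oldest point dropped, and the fit rolled
forward until reference survival is near zero (the *rolling extrapolation
algorithm*). Uncertainty comes from a patient-level bootstrap with
referents regenerated per resample, and group contrasts use z-tests.

Because the registries this method is designed for are access-restricted,
the package ships a synthetic registry generator (`synthetic_scenario()`,
`draw_registry()`) that emulates their statistical structure — staggered
diagnosis years, administrative censoring, group-specific proportional
excess mortality, right-skewed monthly costs with end-of-life
escalation — with exact ground truth computed by quadrature, so every stage
of the pipeline is validated against known answers.

## Worked example

```r
library(lexcost)

sc  <- synthetic_scenario()          # registered default: n = 10,000
reg <- draw_registry(sc, seed = 7)   # records + cost vectors + life table
rep <- run_analysis(reg$records, reg$life_table)
print(rep)
cat("\ntruth: LE", round(mean(reg$truth$le), 2),
    " loss", round(mean(reg$truth$ref_le - reg$truth$le), 2),
    " cost", round(mean(reg$truth$lifetime_cost)), "\n")
```

```
Lifetime analysis report
  settings: 3 knots, stop_eps 0.0001, discount 3.0%/y, B = 0, seed = 1
             stratum     N        deaths           men           age    LE
1 without_depression 9,630 1,528 (15.9%) 2,271 (23.6%) 53.15 ± 13.81 27.46
2    with_depression   370    79 (21.4%)    85 (23.0%) 52.67 ± 13.62 23.24
3   major_depression   116    22 (19.0%)    31 (26.7%) 51.91 ± 12.84 24.08
4   minor_depression   254    57 (22.4%)    54 (21.3%) 53.01 ± 13.98 28.08
  loss_LE lifetime_cost cost_per_year
1    4.90         62507          2276
2    9.61         53636          2308
3    9.13         57442          2385
4    4.60         57795          2058

truth: LE 27.39  loss 4.98  cost 63096
```

Reading the main row: the 9,630 patients without depression have an
estimated life expectancy of 27.46 years after diagnosis, losing 4.90 years
relative to their demographically matched reference population, with an
expected discounted lifetime healthcare cost of 62,507 (2017 USD), i.e.
2,276 USD per life-year. The last line is the generator's ground truth for
this seed — the pipeline recovers LE, loss-of-LE and lifetime cost within
its sampling noise. The depression strata contain only a few hundred
(major: 116) patients, so their single-draw estimates are noisy; run with
`analysis_config(B = 200)` to get bootstrap SEs and percentile CIs
attached, plus z-tests contrasting the with- and without-depression
strata.

`run_analysis()` wraps exported pieces that can be used on their own:
`fit_km()`, `expected_reference_survival()` /
`simulate_reference_cohort()`, `rolling_extrapolate()`,
`mean_monthly_cost()` → `smooth_and_extend_cost()` → `lifetime_cost()`,
`cpi_adjust()`, `resample_ci()`, `z_test()`. Input schemas for patient,
cost, life-table and CPI CSVs are documented in `read_patients()`,
`attach_costs()`, `load_life_table()` and `cpi_series()`; the methods
vignette (`vignettes/lifetime-estimates.Rmd`) explains the model,
parameters and numerical conventions.

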