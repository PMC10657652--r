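# Orchestration: stratified estimation of LE, loss-of-LE and lifetime cost
# with bootstrap uncertainty and group contrasts, producing result tables
# shaped like the standard cohort-registry reports.

#' Analysis configuration
#'
#' Collects every tunable setting of the pipeline; the returned object is
#' echoed in the report so each run records the full set of conventions in
#' effect.
#'
#' @param n_knots spline knots per rolling window. Default 3.
#' @param stop_eps reference-survival stopping threshold. Default `1e-4`.
#' @param age_cap terminal age bounding the extrapolation horizon.
#'   Default 110.
#' @param cost_window trailing cost-smoothing window, months. Default 12.
#' @param discount annual discount rate for costs. Default 0.03.
#' @param B bootstrap resamples (0 = point estimates only). Default 0.
#' @param seed integer seed used by the bootstrap (and Monte-Carlo referents
#'   when selected).
#' @param conf confidence level. Default 0.95.
#' @param min_dx_year if non-`NULL`, restrict to diagnoses in or after this
#'   year before any estimation (sensitivity filter).
#' @param ref_method `"expected"` (exact expectation over referents, the
#'   default) or `"montecarlo"` (simulated referents, as in classical
#'   practice; converges to the expectation).
#' @param mc_replicates referents per patient when `ref_method =
#'   "montecarlo"`. Default 100.
#' @param with_costs estimate lifetime costs (requires cost vectors).
#'   Default `TRUE` when costs are present.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(n_knots = 3L, stop_eps = 1e-4, age_cap = 110L,
                            cost_window = 12L, discount = 0.03, B = 0L,
                            seed = 1L, conf = 0.95, min_dx_year = NULL,
                            ref_method = c("expected", "montecarlo"),
                            mc_replicates = 100L, with_costs = NULL) {
  ref_method <- match.arg(ref_method)
  stopifnot(discount >= 0, B >= 0, n_knots >= 3, stop_eps > 0)
  structure(list(n_knots = n_knots, stop_eps = stop_eps, age_cap = age_cap,
                 cost_window = cost_window, discount = discount, B = B,
                 seed = seed, conf = conf, min_dx_year = min_dx_year,
                 ref_method = ref_method, mc_replicates = mc_replicates,
                 with_costs = with_costs),
            class = "analysis_config")
}

#' Standard strata of a registry cohort
#'
#' Named logical row-selections for the usual report rows: depression status
#' and subtype, sex, and age bands `<50`, `50-64`, `>=65` (which partition
#' the adult cohort).
#'
#' @param records patient records.
#' @param by any of `"depression"`, `"sex"`, `"age_band"`.
#' @return named list of logical vectors.
#' @export
table1_strata <- function(records, by = "depression") {
  out <- list()
  if ("depression" %in% by) {
    d <- records$depression
    out$without_depression <- d == "none"
    out$with_depression <- d != "none"
    out$major_depression <- d == "major"
    out$minor_depression <- d == "minor"
  }
  if ("sex" %in% by) {
    out$male <- records$sex == "M"
    out$female <- records$sex == "F"
  }
  if ("age_band" %in% by) {
    a <- records$age_at_dx
    out$age_lt50 <- a < 50
    out$age_50_64 <- a >= 50 & a < 65
    out$age_ge65 <- a >= 65
  }
  out
}

#' Descriptive summary of a stratum
#'
#' Counts of patients, deaths and men with percentages (one decimal), and
#' age at diagnosis as mean and SD (two decimals), formatted the way the
#' standard report tables print them.
#'
#' @param records patient records.
#' @param stratum as in [fit_km()].
#' @return one-row data frame with numeric columns (`N`, `deaths`, `men`,
#'   `age_mean`, `age_sd`) and display strings (`deaths_fmt`, `men_fmt`,
#'   `age_fmt`).
#' @export
summarize_stratum <- function(records, stratum = NULL) {
  recs <- subset_stratum(records, stratum)
  if (nrow(recs) == 0L) stop("empty stratum")
  N <- nrow(recs)
  deaths <- sum(recs$event == 1)
  men <- sum(recs$sex == "M")
  data.frame(N = N, deaths = deaths, men = men,
             age_mean = mean(recs$age_at_dx), age_sd = sd(recs$age_at_dx),
             deaths_fmt = format_count_pct(deaths, N),
             men_fmt = format_count_pct(men, N),
             age_fmt = sprintf("%.2f ± %.2f", mean(recs$age_at_dx),
                               sd(recs$age_at_dx)),
             stringsAsFactors = FALSE)
}

# single-stratum estimation chain; S_ref_mat reused across bootstrap draws
estimate_stratum <- function(recs, lt, config, stratum_name) {
  res <- try({
    km <- fit_km(recs)
    profiles <- referent_profiles(recs)
    # +12: the terminal q = 1 year drives reference survival to zero
    H <- max((config$age_cap - recs$age_at_dx) * 12L) + 12L
    rs <- reference_survival_matrix(profiles, lt, H)
    ref <- if (config$ref_method == "montecarlo")
      simulate_reference_cohort(profiles, lt, H,
                                replicates_per_profile = config$mc_replicates,
                                seed = config$seed)
    else
      survival_curve(0:H, drop(rs$weight %*% rs$S) / sum(rs$weight),
                     type = "reference")
    ex <- rolling_extrapolate(km, ref, n_knots = config$n_knots,
                              stop_eps = config$stop_eps)
    with_costs <- config$with_costs %||% !is.null(recs$costs)
    lc <- NULL
    if (with_costs) {
      cc <- mean_monthly_cost(recs)
      ch <- smooth_and_extend_cost(cc, config$cost_window, ex$stop_month)
      lc <- lifetime_cost(ex$curve, ch, config$discount)
    }
    list(km = km, ref = ref, ex = ex, lc = lc, rs = rs, H = H)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("stratum '", stratum_name, "': ", attr(res, "condition")$message)
  res
}

# estimates vector used both for the point estimate and inside the bootstrap
stratum_estimates <- function(km, ex, lc) {
  c(LE = ex$LE, loss_LE = ex$loss_of_LE,
    lifetime_cost = if (!is.null(lc)) lc$lifetime_cost else NA_real_,
    cost_per_year = if (!is.null(lc)) lc$cost_per_life_year else NA_real_)
}

#' Run the full stratified lifetime analysis
#'
#' For every stratum: monthly Kaplan-Meier, matched reference curve from the
#' life table, rolling restricted-cubic-spline extrapolation, LE /
#' loss-of-LE, and (when costs are attached) smoothed mean monthly cost and
#' survival-weighted discounted lifetime cost. With `config$B > 0`,
#' patient-level bootstrap SEs and percentile CIs are added (referents are
#' regenerated for each resample), and z-tests contrast loss-of-LE and cost
#' per life-year between with- and without-depression strata.
#'
#' @param records patient records (with a `costs` list column for cost
#'   estimation).
#' @param lt a `"life_table"`.
#' @param config an [analysis_config()].
#' @param strata named list of logical row-selections or predicate
#'   functions `records -> logical` (evaluated after any dx-year filter);
#'   default [table1_strata()] on depression status.
#' @return object of class `"lexcost_report"`: list with `results` (one row
#'   per stratum), `summaries`, `curves`, `uncertainty`, `comparisons`, and
#'   `settings`.
#' @export
run_analysis <- function(records, lt, config = analysis_config(),
                         strata = NULL) {
  validate_records(records)
  if (!is.null(config$min_dx_year))
    records <- restrict_cohort(records, config$min_dx_year)
  if (nrow(records) == 0L) stop("no records left after the dx-year filter")
  if (is.null(strata)) strata <- table1_strata(records, "depression")
  currency <- attr(records, "cost_currency")
  rows <- list(); summaries <- list(); curves <- list(); unc <- list()
  for (nm in names(strata)) {
    sel <- strata[[nm]]
    if (is.function(sel)) sel <- sel(records)
    if (!any(sel)) { message("skipping empty stratum '", nm, "'"); next }
    recs <- subset_stratum(records, sel)
    fit <- estimate_stratum(recs, lt, config, nm)
    est <- stratum_estimates(fit$km, fit$ex, fit$lc)
    se <- rep(NA_real_, length(est)); names(se) <- names(est)
    ci <- NULL
    if (config$B > 0L) {
      recs$.pidx <- fit$rs$index
      S <- fit$rs$S; H <- fit$H; cfg <- config; cur <- currency
      boot_fun <- function(r) {
        attr(r, "cost_currency") <- cur
        w <- tabulate(r$.pidx, nbins = nrow(S))
        ref <- survival_curve(0:H, drop(w %*% S) / sum(w),
                              type = "reference")
        km <- fit_km(r)
        ex <- rolling_extrapolate(km, ref, n_knots = cfg$n_knots,
                                  stop_eps = cfg$stop_eps)
        lc <- NULL
        if (!is.null(r$costs) && (cfg$with_costs %||% TRUE)) {
          cc <- mean_monthly_cost(r)
          ch <- smooth_and_extend_cost(cc, cfg$cost_window, ex$stop_month)
          lc <- lifetime_cost(ex$curve, ch, cfg$discount)
        }
        stratum_estimates(km, ex, lc)
      }
      u <- resample_ci(recs, boot_fun, B = config$B,
                       seed = config$seed + match(nm, names(strata)),
                       conf = config$conf)
      se <- u$se; ci <- u$ci; unc[[nm]] <- u
    }
    rows[[nm]] <- data.frame(
      stratum = nm, N = nrow(recs), deaths = sum(recs$event == 1),
      LE = unname(est["LE"]), LE_se = unname(se["LE"]),
      loss_LE = unname(est["loss_LE"]), loss_LE_se = unname(se["loss_LE"]),
      lifetime_cost = unname(est["lifetime_cost"]),
      lifetime_cost_se = unname(se["lifetime_cost"]),
      cost_per_year = unname(est["cost_per_year"]),
      cost_per_year_se = unname(se["cost_per_year"]),
      stop_month = fit$ex$stop_month, stringsAsFactors = FALSE)
    summaries[[nm]] <- cbind(stratum = nm, summarize_stratum(recs))
    curves[[nm]] <- list(km = fit$km, ref = fit$ref,
                         extrapolated = fit$ex$curve)
  }
  if (!length(rows)) stop("no non-empty strata")
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  comparisons <- NULL
  if (config$B > 0L &&
      all(c("with_depression", "without_depression") %in% results$stratum)) {
    a <- results[results$stratum == "with_depression", ]
    b <- results[results$stratum == "without_depression", ]
    cmp <- list()
    for (qy in c("loss_LE", "cost_per_year")) {
      se_a <- a[[paste0(qy, "_se")]]; se_b <- b[[paste0(qy, "_se")]]
      if (is.finite(se_a) && is.finite(se_b) && se_a > 0 && se_b > 0) {
        zt <- z_test(a[[qy]], se_a, b[[qy]], se_b)
        cmp[[qy]] <- data.frame(quantity = qy,
                                diff = a[[qy]] - b[[qy]],
                                z = zt$z, p = zt$p)
      }
    }
    if (length(cmp)) comparisons <- do.call(rbind, cmp)
  }
  structure(list(results = results,
                 summaries = do.call(rbind, summaries),
                 curves = curves, uncertainty = unc,
                 comparisons = comparisons, settings = config),
            class = "lexcost_report")
}

#' @export
print.lexcost_report <- function(x, ...) {
  cat("Lifetime analysis report\n")
  cat(sprintf("  settings: %d knots, stop_eps %g, discount %.1f%%/y, B = %d, seed = %d\n",
              x$settings$n_knots, x$settings$stop_eps,
              100 * x$settings$discount, x$settings$B, x$settings$seed))
  print(format_results(x))
  if (!is.null(x$comparisons)) {
    cat("with- vs without-depression contrasts (z-test):\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Display-rounded results table
#'
#' Full-precision estimates live in `report$results`; this renders the
#' report-style view (LE and loss-of-LE to two decimals, costs to whole
#' currency units, percentages to one decimal).
#'
#' @param report a `"lexcost_report"`.
#' @return data frame of formatted strings.
#' @export
format_results <- function(report) {
  r <- report$results
  s <- report$summaries[match(r$stratum, report$summaries$stratum), ]
  fmt_se <- function(v, se, d) {
    ifelse(is.finite(se), sprintf(paste0("%.", d, "f (%.", d, "f)"), v, se),
           sprintf(paste0("%.", d, "f"), v))
  }
  data.frame(stratum = r$stratum,
             N = formatC(r$N, format = "d", big.mark = ","),
             deaths = s$deaths_fmt, men = s$men_fmt, age = s$age_fmt,
             LE = fmt_se(r$LE, r$LE_se, 2),
             loss_LE = fmt_se(r$loss_LE, r$loss_LE_se, 2),
             lifetime_cost = fmt_se(r$lifetime_cost, r$lifetime_cost_se, 0),
             cost_per_year = sprintf("%.0f", r$cost_per_year),
             stringsAsFactors = FALSE)
}

#' Write the full-precision results table to CSV
#'
#' @param report a `"lexcost_report"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(report, path) {
  write.csv(report$results, path, row.names = FALSE)
  invisible(path)
}
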