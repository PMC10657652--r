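# Patient-level nonparametric bootstrap for uncertainty of LE, loss-of-LE
# and lifetime-cost estimates. Patients are resampled with replacement;
# the analysis callable re-runs the full chain on each resample (including
# regeneration of the matched referents, since referent profiles derive from
# the resampled patients).

#' Bootstrap standard errors and percentile confidence intervals
#'
#' @param records patient records.
#' @param analysis function taking a records data frame and returning a
#'   numeric vector (possibly named) of estimates; must be deterministic
#'   given its input.
#' @param B number of bootstrap resamples (>= 2).
#' @param seed integer seed (required).
#' @param conf confidence level for the percentile interval. Default 0.95.
#' @return object of class `"uncertainty_result"`: list with `estimate`
#'   (full-sample), `se`, `ci` (2 x k matrix of percentile bounds), `B`,
#'   `n_failed` (replicates that errored, excluded from the summaries),
#'   `seed`, and `replicates` (B_ok x k matrix).
#' @export
resample_ci <- function(records, analysis, B = 200L, seed, conf = 0.95) {
  stopifnot(B >= 2L)
  if (missing(seed)) stop("'seed' is required")
  est0 <- analysis(records)
  k <- length(est0)
  n <- nrow(records)
  set.seed(seed)
  reps <- matrix(NA_real_, nrow = B, ncol = k,
                 dimnames = list(NULL, names(est0)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    r <- try(analysis(records[idx, , drop = FALSE]), silent = TRUE)
    if (inherits(r, "try-error") || length(r) != k || anyNA(r)) {
      n_failed <- n_failed + 1L
    } else {
      reps[b, ] <- r
    }
  }
  ok <- reps[stats::complete.cases(reps), , drop = FALSE]
  if (nrow(ok) == 0L) stop("all bootstrap replicates failed")
  a <- (1 - conf) / 2
  ci <- apply(ok, 2L, quantile, probs = c(a, 1 - a), names = FALSE)
  structure(list(estimate = est0, se = apply(ok, 2L, sd),
                 ci = matrix(ci, nrow = 2L,
                             dimnames = list(c("lower", "upper"),
                                             names(est0))),
                 B = B, n_failed = n_failed, seed = seed, conf = conf,
                 replicates = ok),
            class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf("<uncertainty_result: B = %d (%d failed), %d%% percentile CI>\n",
              x$B, x$n_failed, round(100 * x$conf)))
  est <- rbind(estimate = x$estimate, se = x$se, x$ci)
  print(round(est, 4))
  invisible(x)
}
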