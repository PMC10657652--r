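# Lifetime extrapolation of a cohort survival curve via the rolling
# restricted-cubic-spline algorithm on the transformed relative survival
# ratio.
#
# Under a proportional excess hazard the ratio S_index(t)/S_ref(t) decays
# log-linearly, so its log (exactly) and its logit (asymptotically) are
# linear in the tail; a restricted cubic spline (linear beyond the boundary
# knots) fitted to the observed window extrapolates one month at a time.

#' Logit relative survival series
#'
#' Computes `W(t) = logit(S_index(t) / S_ref(t))` on the observed window.
#' The ratio is clipped into `[eps, 1 - eps]` before the logit so the series
#' is finite everywhere (in particular `W(0) = logit(1 - eps)` since both
#' curves start at 1).
#'
#' @param km observed [survival_curve()] (e.g. from [fit_km()]).
#' @param ref reference [survival_curve()] on the same monthly grid, at least
#'   as long as `km` and positive over the observed window.
#' @param eps clipping constant. Default `1e-6`.
#' @return data frame of class `"logit_rel_surv"` with columns `month`, `W`.
#' @export
logit_relative_survival <- function(km, ref, eps = 1e-6) {
  Tm <- max(km$month)
  if (max(ref$month) < Tm)
    stop("grid mismatch: reference curve shorter than the observed curve")
  if (!identical(as.integer(ref$month[seq_len(Tm + 1L)]),
                 as.integer(km$month)))
    stop("grid mismatch: curves are not on the same monthly grid")
  s_ref <- ref$survival[seq_len(Tm + 1L)]
  if (any(s_ref <= 0))
    stop("reference survival must be positive over the observed window")
  r <- pmin(pmax(km$survival / s_ref, eps), 1 - eps)
  out <- data.frame(month = km$month, W = qlogis(r))
  class(out) <- c("logit_rel_surv", "data.frame")
  out
}

#' Rolling restricted-cubic-spline extrapolation to the lifetime horizon
#'
#' Maintains a sliding window of transformed relative survival values whose
#' length equals the observed follow-up. At each step a restricted cubic
#' spline is fitted to the window by weighted least squares, the next
#' month's value is predicted on the spline's linear tail, converted back to
#' survival (multiplying the back-transformed ratio by the reference curve)
#' and clamped to be nonincreasing; the prediction is appended and the
#' window's oldest point dropped. Iteration stops when the reference
#' survival falls below `stop_eps` or the reference curve ends (the age cap
#' encoded in its horizon).
#'
#' Two fitting scales are available. The default, `transform = "log"`, fits
#' the spline to `log(S_index/S_ref)`: this quantity is *exactly* linear in
#' time under a constant excess hazard, its sampling noise is not amplified
#' as the ratio approaches 1, it needs no clipping (ratios above 1 from
#' sampling noise enter as positive values, and the ratio is bounded at 1
#' only when converting predictions back to survival), and its
#' inverse-variance weights `1/G(t)` — with `G` a cumulative-information
#' factor proportional to elapsed time, held at its last observed value for
#' appended predictions — do not depend on the estimated ratio.
#' `transform = "logit"` fits the classical logit of the ratio instead; the
#' logit diverges for ratios statistically indistinguishable from 1, which
#' makes its least-squares extrapolation unstable for cohorts with little
#' or no excess mortality, so the logit series is winsorized at the
#' window's own noise scale and precision-weighted by
#' `(1 - r)^2 / G(t)` (delta method). Both scales coincide to first order
#' wherever the ratio is bounded away from 1.
#'
#' Life expectancy is the area under the extrapolated curve (trapezoidal rule
#' on the monthly grid, reported in years); the reference life expectancy is
#' the same area under the reference curve, and the loss of life expectancy
#' their difference (exact by construction).
#'
#' @param km observed [survival_curve()]; at least 24 months of follow-up.
#' @param ref_full reference [survival_curve()] extending to the lifetime
#'   horizon (ideally until its survival drops below `stop_eps`).
#' @param n_knots spline knots per window. Default 3: on the log scale the
#'   extrapolated quantity is near-linear, and additional knots add variance
#'   without reducing bias.
#' @param stop_eps reference-survival stopping threshold. Default `1e-4`.
#' @param eps ratio clipping constant. Default `1e-6`.
#' @param weighting `"ivw"` (inverse-variance, the default) or `"equal"`.
#' @param min_at_risk when the observed curve carries at-risk counts, the
#'   window is truncated at the last month with at least this many subjects
#'   at risk (subject to the 24-month minimum): product-limit tails
#'   estimated from a handful of survivors carry enormous variance on any
#'   transformed scale and would otherwise dominate the most-informative
#'   end of the window. Default 30; set to 0 to disable.
#' @param knot_probs optional custom knot quantiles (see [rcs_knots()]).
#' @param transform fitting scale, `"log"` (default) or `"logit"`; see
#'   Details.
#' @return an object of class `"extrapolation_result"`: list with `curve`
#'   (data frame `month`, `survival`, `source` = observed/extrapolated),
#'   `ref` (reference curve on the same grid), `LE`, `LE_ref`, `loss_of_LE`
#'   (years), `stop_month`, `stop_reason`, and the settings used.
#' @export
rolling_extrapolate <- function(km, ref_full, n_knots = 3L, stop_eps = 1e-4,
                                eps = 1e-6, weighting = c("ivw", "equal"),
                                min_at_risk = 30L, knot_probs = NULL,
                                transform = c("log", "logit")) {
  weighting <- match.arg(weighting)
  transform <- match.arg(transform)
  if (min_at_risk > 0L && "n_at_risk" %in% names(km)) {
    ok <- which(km$n_at_risk >= min_at_risk)
    # never truncate below the 24-month minimum window
    keep <- if (length(ok)) max(max(ok), 24L) else min(nrow(km), 24L)
    if (keep < nrow(km)) km <- km[seq_len(keep), , drop = FALSE]
  }
  Tm <- max(km$month)
  if (Tm + 1L < 24L)
    stop("observed window too short: need at least 24 months of follow-up")
  H <- max(ref_full$month)
  if (H <= Tm) stop("reference curve too short for extrapolation")
  s_ref <- ref_full$survival            # index: month m -> s_ref[m + 1]
  W <- logit_relative_survival(km, ref_full, eps = eps)$W
  L <- Tm + 1L                          # window length
  u <- 0:(L - 1L)
  knots <- rcs_knots(u, n_knots, probs = knot_probs)
  X <- rcs_basis(u, knots)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient spline window")
  xp <- drop(rcs_basis(L, knots))
  # cumulative-information factor: smooth time proxy (see Details)
  G <- pmax(0:Tm, 1)
  G_last <- G[L]
  p <- ncol(X)
  # per-point weights slide with the window, so maintain them incrementally;
  # the normal-equation matrix is assembled as M %*% w with M the stacked
  # outer products of the basis rows
  M <- matrix(apply(X, 1L, tcrossprod), ncol = L)
  if (transform == "log") {
    # log relative survival: exactly linear under constant excess hazard,
    # noise scale not amplified near r = 1, no clipping artefacts; ratios
    # above 1 (sampling noise) enter as positive values and predictions are
    # capped at 0 (r <= 1)
    ratio <- km$survival / s_ref[seq_len(L)]
    win <- log(pmax(ratio, eps))
    # predictions stay uncapped in the rollout state (capping each step at
    # log 1 = 0 would truncate upward noise and ratchet the null case
    # downward); the ratio is bounded at 1 only when converting to survival
    cap <- Inf
    wt_of <- function(val, g) 1 / g
    to_surv <- function(val, sr) pmin(exp(val), 1) * sr
  } else {
    # logit scale as in the classical formulation; the series is winsorized
    # at logit(1 - delta) with delta the median observed deviation of the
    # ratio from 1, because logit magnitudes inside the window's noise band
    # around 1 are meaningless and destabilize the rollout
    delta <- max(eps, stats::median(pmax(1 - plogis(W), 0)))
    cap <- qlogis(1 - delta)
    win <- pmin(W, cap)
    wt_of <- function(val, g) (1 - plogis(val))^2 / g
    to_surv <- function(val, sr) plogis(val) * sr
  }
  s_ext <- c(km$survival, rep(NA_real_, H - Tm))
  w <- if (weighting == "ivw") wt_of(win, G) else rep(1, L)
  stop_reason <- "horizon_end"
  t_stop <- H
  for (m in (Tm + 1L):H) {
    if (s_ref[m + 1L] < stop_eps) {
      t_stop <- m - 1L
      stop_reason <- "ref_below_eps"
      break
    }
    A <- matrix(M %*% w, p, p)
    beta <- solve(A + diag(1e-9 * mean(diag(A)), p),
                  crossprod(X, w * win))
    w_pred <- min(sum(xp * beta), cap)
    s_new <- min(to_surv(w_pred, s_ref[m + 1L]), s_ext[m])
    s_ext[m + 1L] <- s_new
    win <- c(win[-1L], w_pred)
    w <- c(w[-1L], if (weighting == "ivw") wt_of(w_pred, G_last) else 1)
  }
  grid <- 0:t_stop
  s_out <- s_ext[grid + 1L]
  le <- trapz_years(s_out)
  le_ref <- trapz_years(s_ref[grid + 1L])
  structure(list(
    curve = data.frame(month = grid, survival = s_out,
                       source = ifelse(grid <= Tm, "observed",
                                       "extrapolated")),
    ref = data.frame(month = grid, survival = s_ref[grid + 1L]),
    LE = le, LE_ref = le_ref, loss_of_LE = le_ref - le,
    stop_month = t_stop, stop_reason = stop_reason,
    observed_months = Tm, n_knots = n_knots, stop_eps = stop_eps,
    weighting = weighting, transform = transform),
    class = "extrapolation_result")
}

#' @export
print.extrapolation_result <- function(x, ...) {
  cat(sprintf(paste0("<extrapolation_result: LE %.2f y, reference LE %.2f y,",
                     " loss-of-LE %.2f y; observed %d m, stopped at %d m",
                     " (%s)>\n"),
              x$LE, x$LE_ref, x$loss_of_LE, x$observed_months, x$stop_month,
              x$stop_reason))
  invisible(x)
}

#' Two-sample z-test from estimates and standard errors
#'
#' `z = (est1 - est2) / sqrt(se1^2 + se2^2)` with a two-sided normal p-value,
#' used to contrast loss-of-LE or cost estimates between strata.
#'
#' @param est1,se1 estimate and standard error of group 1.
#' @param est2,se2 estimate and standard error of group 2.
#' @return list with elements `z` and `p`.
#' @export
#' @examples
#' z_test(5.60, 1.85, 4.76, 0.60)  # p ~ 0.666
z_test <- function(est1, se1, est2, se2) {
  if (!is.finite(se1) || !is.finite(se2) || se1 <= 0 || se2 <= 0)
    stop("standard errors must be positive")
  z <- (est1 - est2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}
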