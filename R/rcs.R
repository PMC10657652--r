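# Restricted cubic splines (natural cubic splines): cubic between knots,
# linear beyond the boundary knots, C2 at every knot. The truncated-power
# restricted basis (Harrell parameterisation) is used, scaled by the squared
# knot span so coefficients stay well conditioned.

#' Knot locations for a restricted cubic spline
#'
#' Boundary knots at the 5th and 95th percentiles of the time points; by
#' default the interior knots are equally spaced between them. Alternatively
#' `probs` places all knots at arbitrary quantiles, e.g. front-loaded
#' positions when the curvature is known to sit early in the series.
#'
#' @param t numeric vector of time points.
#' @param n_knots total number of knots (>= 3); ignored when `probs` given.
#' @param probs optional quantile positions of all knots (increasing, in
#'   `[0, 1]`).
#' @return strictly increasing numeric vector of knots.
#' @export
rcs_knots <- function(t, n_knots = 5L, probs = NULL) {
  if (is.null(probs)) {
    stopifnot(n_knots >= 3L)
    b <- unname(quantile(t, c(0.05, 0.95), names = FALSE))
    k <- seq(b[1L], b[2L], length.out = n_knots)
  } else {
    stopifnot(length(probs) >= 3L)
    k <- unname(quantile(t, probs, names = FALSE))
  }
  if (any(diff(k) <= 0))
    stop("knots are not strictly increasing; too few distinct time points")
  k
}

#' Restricted cubic spline design matrix
#'
#' Columns: intercept, `t`, and `n_knots - 2` restricted truncated-power
#' terms. The restriction cancels the quadratic and cubic terms beyond the
#' last knot, so predictions are linear in `t` outside the boundary knots.
#'
#' @param t evaluation points.
#' @param knots strictly increasing knot vector (length >= 3).
#' @return numeric matrix with `length(t)` rows and `length(knots)` columns.
#' @export
rcs_basis <- function(t, knots) {
  K <- length(knots)
  stopifnot(K >= 3L, all(diff(knots) > 0))
  kK <- knots[K]; kK1 <- knots[K - 1L]
  scale <- (kK - knots[1L])^2
  pp <- function(x) pmax(x, 0)^3
  X <- matrix(0, nrow = length(t), ncol = K)
  X[, 1L] <- 1
  X[, 2L] <- t
  for (j in seq_len(K - 2L)) {
    kj <- knots[j]
    X[, j + 2L] <- (pp(t - kj) -
                      pp(t - kK1) * (kK - kj) / (kK - kK1) +
                      pp(t - kK) * (kK1 - kj) / (kK - kK1)) / scale
  }
  X
}

#' Fit a restricted cubic spline to a logit relative survival series
#'
#' Ordinary least squares of `W(t)` on the restricted cubic basis with knots
#' from [rcs_knots()]. Used both standalone and (implicitly) at every step of
#' [rolling_extrapolate()].
#'
#' @param series data frame with columns `month` and `W` (e.g. from
#'   [logit_relative_survival()]).
#' @param n_knots number of knots. Default 5.
#' @return an object of class `"rcs_fit"` with elements `knots`, `coef`.
#' @export
fit_rcs <- function(series, n_knots = 5L) {
  t <- series$month; w <- series$W
  if (length(t) < n_knots + 2L)
    stop("series too short for ", n_knots, " knots")
  knots <- rcs_knots(t, n_knots)
  X <- rcs_basis(t, knots)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient spline fit (too few distinct time points)")
  structure(list(knots = knots, coef = qr.coef(qx, w), n_knots = n_knots),
            class = "rcs_fit")
}

#' Predict from a fitted restricted cubic spline
#'
#' @param object an `"rcs_fit"`.
#' @param newmonths time points at which to predict (may lie beyond the data;
#'   predictions there follow the linear tails).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.rcs_fit <- function(object, newmonths, ...) {
  drop(rcs_basis(newmonths, object$knots) %*% object$coef)
}
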