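# Biomarker-response model on the quantile scale.
#
# All modelling is done after transforming the raw biomarker to its
# population quantile B, so that B ~ Unif[0,1] in the unscreened population.
# pi(B) is the point response rate at quantile B (logistic in B) and Pi(B)
# is the mean response rate in the enriched subpopulation {quantile >= B}.

#' Logistic biomarker-response curve
#'
#' Constructs the response model used throughout the package: a logistic
#' curve on the biomarker quantile scale, with linear predictor
#' `delta0 + delta1 * B`. `delta1` is the log odds ratio of response per
#' unit of biomarker quantile; `delta0` the log-odds of response at `B = 0`.
#'
#' @param delta0 Intercept (log-odds of response at quantile 0).
#' @param delta1 Slope (log odds ratio per unit quantile). Positive values
#'   encode the assumed monotone increasing biomarker-response association;
#'   for a negative association flip the sign of the biomarker first.
#' @return An object of class `cbatt_curve`.
#' @examples
#' curve <- logistic_curve(-3, 6)
#' response_rate(curve, c(0, 0.5, 1))
#' subset_rate(curve, c(0, 0.5, 0.95))
#' @export
logistic_curve <- function(delta0, delta1) {
  if (!is.numeric(delta0) || length(delta0) != 1L || !is.finite(delta0) ||
      !is.numeric(delta1) || length(delta1) != 1L || !is.finite(delta1)) {
    stop("`delta0` and `delta1` must be single finite numbers.", call. = FALSE)
  }
  structure(list(delta0 = as.numeric(delta0), delta1 = as.numeric(delta1)),
            class = "cbatt_curve")
}

#' @export
print.cbatt_curve <- function(x, ...) {
  cat(sprintf("<cbatt_curve> logit pi(B) = %.4g + %.4g B\n", x$delta0, x$delta1))
  cat(sprintf("  pi(0) = %.3f, pi(1) = %.3f, Pi(0) = %.3f\n",
              response_rate(x, 0), response_rate(x, 1), subset_rate(x, 0)))
  invisible(x)
}

# Numerically stable log(1 + exp(x)) for any x (|x| can exceed 700 in
# extreme coefficient draws): max(x, 0) + log1p(exp(-|x|)) never overflows
# and is exact to double precision.
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

check_quantile <- function(b, arg = "b") {
  if (!is.numeric(b) || anyNA(b) || any(b < 0 | b > 1)) {
    stop(sprintf("`%s` must be numeric in [0, 1].", arg), call. = FALSE)
  }
  b
}

# Point response rate for vectors of coefficients/quantiles (recycled).
pi_point <- function(delta0, delta1, b) {
  stats::plogis(delta0 + delta1 * b)
}

# Subset response rate Pi(B) = mean of pi over (B, 1] for B ~ Unif[0,1]:
#   Pi(B) = [log(1 + e^(d0 + d1)) - log(1 + e^(d0 + d1 B))] / (d1 (1 - B)).
# The closed form divides by d1 (1 - B); when that width is small the two
# log1pexp terms cancel catastrophically, so we switch to the midpoint rule
# Pi(B) ~= expit(d0 + d1 (1 + B) / 2), whose error is O((d1 (1 - B))^2 / 24)
# and which contains both analytic limits (d1 -> 0 and B -> 1) exactly.
pi_subset <- function(delta0, delta1, b) {
  n <- max(length(delta0), length(delta1), length(b))
  delta0 <- rep_len(delta0, n)
  delta1 <- rep_len(delta1, n)
  b <- rep_len(b, n)
  h <- delta1 * (1 - b)
  out <- numeric(n)
  small <- abs(h) < 1e-4
  if (any(small)) {
    out[small] <- stats::plogis(delta0[small] + delta1[small] * (1 + b[small]) / 2)
  }
  if (any(!small)) {
    d0 <- delta0[!small]; d1 <- delta1[!small]; bb <- b[!small]
    out[!small] <- (log1pexp(d0 + d1) - log1pexp(d0 + d1 * bb)) / (d1 * (1 - bb))
  }
  out
}

#' Point response rate pi(B)
#'
#' The probability of response at a single biomarker quantile `b`,
#' `exp(z)/(1 + exp(z))` with `z = delta0 + delta1 * b`, evaluated
#' overflow-safely.
#'
#' @param curve A [logistic_curve()].
#' @param b Vector of biomarker quantiles in `[0, 1]`.
#' @return Numeric vector of response rates in `(0, 1)`.
#' @export
response_rate <- function(curve, b) {
  stopifnot(inherits(curve, "cbatt_curve"))
  check_quantile(b)
  pi_point(curve$delta0, curve$delta1, b)
}

#' Subset response rate Pi(B)
#'
#' The mean response rate in the enriched subpopulation with biomarker
#' quantile at least `b`, assuming quantiles are uniform on `[0, 1]`:
#' the average of [response_rate()] over `(b, 1]`, available in closed form
#' for the logistic model. At `b = 1` the limiting value `pi(1)` is
#' returned; for slopes (or integration widths) small enough that the
#' closed form loses precision, an equivalent midpoint approximation with
#' error below 1e-9 is used, which reduces to `plogis(delta0)` as
#' `delta1 -> 0`.
#'
#' @inheritParams response_rate
#' @return Numeric vector of subset response rates in `(0, 1)`.
#' @export
subset_rate <- function(curve, b) {
  stopifnot(inherits(curve, "cbatt_curve"))
  check_quantile(b)
  pi_subset(curve$delta0, curve$delta1, b)
}

#' Calibrate the intercept of a response curve
#'
#' Solves for the intercept `delta0` such that the subset response rate
#' hits a prescribed anchor, `Pi(anchor_b) = anchor_rate`, for a given
#' slope. This is how simulation scenarios with a prescribed true
#' threshold are constructed: a curve with `Pi(T) = rho` has true
#' threshold `T`. `Pi` is strictly increasing in `delta0`, so the root is
#' unique; it is found by Brent's method on `delta0` in `[-50, 50]` to a
#' tolerance of 1e-12.
#'
#' @param delta1 Non-negative slope (log odds ratio per unit quantile).
#' @param anchor_b Quantile in `[0, 1)` at which the subset rate is pinned.
#' @param anchor_rate Target subset response rate in `(0, 1)`.
#' @return A [logistic_curve()] satisfying the anchor.
#' @examples
#' curve <- calibrate_intercept(6, 0.5, 0.4)
#' round(subset_rate(curve, c(0, 0.95)), 2) # 0.22, 0.71
#' @export
calibrate_intercept <- function(delta1, anchor_b, anchor_rate) {
  stopifnot(is.numeric(delta1), length(delta1) == 1L, is.finite(delta1),
            delta1 >= 0)
  check_quantile(anchor_b, "anchor_b")
  if (anchor_b >= 1) stop("`anchor_b` must be strictly below 1.", call. = FALSE)
  if (!is.numeric(anchor_rate) || anchor_rate <= 0 || anchor_rate >= 1) {
    stop("`anchor_rate` must lie in (0, 1).", call. = FALSE)
  }
  if (delta1 < 1e-8) {
    # constant-rate curve: Pi(b) = plogis(delta0) for every b
    return(logistic_curve(stats::qlogis(anchor_rate), delta1))
  }
  f <- function(d0) pi_subset(d0, delta1, anchor_b) - anchor_rate
  lo <- f(-50); hi <- f(50)
  if (lo > 0 || hi < 0) {
    stop("Calibration failed: no intercept in [-50, 50] attains the anchor.",
         call. = FALSE)
  }
  root <- stats::uniroot(f, c(-50, 50), tol = 1e-12)$root
  logistic_curve(root, delta1)
}

#' Calibrate a near-null curve from two subset-rate anchors
#'
#' Solves for both coefficients so that `Pi(0) = pi0` and
#' `Pi(at) = pi_at`. Used for null scenarios in which the subset response
#' rate rises from `pi0` to a value just below the reference rate, so
#' that no qualifying subpopulation exists anywhere on the grid.
#'
#' @param pi0 Subset response rate at quantile 0.
#' @param pi_at Subset response rate at quantile `at`; must exceed `pi0`.
#' @param at Quantile of the second anchor (default 0.95).
#' @return A [logistic_curve()].
#' @export
calibrate_null_curve <- function(pi0, pi_at, at = 0.95) {
  stopifnot(pi0 > 0, pi0 < pi_at, pi_at < 1)
  check_quantile(at, "at")
  gap <- function(delta1) {
    d0 <- calibrate_intercept(delta1, at, pi_at)$delta0
    pi_subset(d0, delta1, 0) - pi0
  }
  root <- stats::uniroot(gap, c(1e-6, 50), tol = 1e-10)$root
  calibrate_intercept(root, at, pi_at)
}

#' Smallest quantile whose subset response rate attains a target
#'
#' Inverts `Pi` for an increasing curve: returns the smallest `B` with
#' `Pi(B) >= rate`. When even `Pi(0)` exceeds the target the boundary 0 is
#' returned (the positive subset should be as large as possible); when the
#' target is never attained on `[0, 1)`, `NA`.
#'
#' @inheritParams response_rate
#' @param rate Target subset response rate.
#' @return A quantile in `[0, 1)`, or `NA_real_`.
#' @export
threshold_for_rate <- function(curve, rate) {
  stopifnot(inherits(curve, "cbatt_curve"))
  if (subset_rate(curve, 0) >= rate) return(0)
  if (subset_rate(curve, 1 - 1e-9) < rate) return(NA_real_)
  stats::uniroot(function(b) subset_rate(curve, b) - rate,
                 c(0, 1 - 1e-9), tol = 1e-10)$root
}

#' Empirical quantile transform of biomarker measurements
#'
#' Maps raw biomarker values to their empirical-CDF position in a
#' reference sample, so that in the reference population the transformed
#' value is approximately Unif\[0,1\]. Convention: quantile = (number of
#' reference values \eqn{\le} x) / n, so the reference maximum maps to 1,
#' values below the reference minimum map to 0, and ties take the maximal
#' rank. The transform is monotone non-decreasing in the raw value.
#'
#' @param values Numeric vector of raw biomarker measurements.
#' @param reference Non-empty numeric vector: the reference biomarker
#'   sample characterising the population distribution.
#' @return Numeric vector of quantiles in `[0, 1]`.
#' @export
quantile_transform <- function(values, reference) {
  if (length(reference) == 0L || !is.numeric(reference) || anyNA(reference)) {
    stop("`reference` must be a non-empty numeric vector without NAs.",
         call. = FALSE)
  }
  stats::ecdf(reference)(values)
}

#' Back-transform a quantile threshold to the raw biomarker scale
#'
#' Returns the smallest reference measurement whose empirical quantile is
#' at least `t_hat` (nearest order statistic; no interpolation).
#'
#' @param t_hat Quantile threshold in `[0, 1]`.
#' @param reference Reference biomarker sample (raw scale).
#' @return A raw-scale biomarker value.
#' @export
raw_threshold <- function(t_hat, reference) {
  check_quantile(t_hat, "t_hat")
  s <- sort(reference)
  s[max(1L, ceiling(t_hat * length(s)))]
}
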