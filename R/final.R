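# End-of-study inference: required response count, binomial exact test,
# and threshold estimation with coefficient-resampling intervals.

#' Minimum responses for a significant trial
#'
#' The smallest integer `x` such that the binomial exact test is
#' significant, `P(X >= x | X ~ Binomial(s, rho)) <= alpha`. Because the
#' trial size, reference rate and level are fixed in advance, this count
#' (`X_H`) is known before the trial starts. Returns `s + 1` when no
#' attainable count is significant.
#'
#' @param s Total trial sample size.
#' @param rho Reference response rate in `[0, 1)`.
#' @param alpha Significance level in `(0, 1]`.
#' @return An integer in `0:(s + 1)`.
#' @examples
#' required_responses(100, 0.4, 0.05) # 49
#' required_responses(70, 0.65, 0.05) # 53
#' @export
required_responses <- function(s, rho, alpha) {
  stopifnot(s >= 1, rho >= 0, rho < 1, alpha > 0, alpha <= 1)
  x <- 0:(s + 1)
  tail <- stats::pbinom(x - 1, s, rho, lower.tail = FALSE)
  as.integer(x[which(tail <= alpha)[1]])
}

#' Binomial exact test for the response rate
#'
#' Upper-tail exact p-value `P(X >= x_ob | X ~ Binomial(s, rho))` for the
#' observed response count against the reference rate.
#'
#' @param x_ob Observed responses, `0 <= x_ob <= s`.
#' @param s Sample size.
#' @param rho Reference response rate.
#' @return The exact p-value.
#' @examples
#' exact_test(53, 70, 0.65) # 0.037
#' @export
exact_test <- function(x_ob, s, rho) {
  stopifnot(x_ob >= 0, x_ob <= s)
  stats::pbinom(x_ob - 1, s, rho, lower.tail = FALSE)
}

# Argmin of |Pi_hat(B) - rho| over the search grid, ties broken toward the
# smaller B (the largest "positive" subset). Vectorised over draws:
# d0, d1 may be vectors, returning one threshold per coefficient pair.
threshold_argmin <- function(d0, d1, rho, grid) {
  n <- max(length(d0), length(d1))
  d0 <- rep_len(d0, n); d1 <- rep_len(d1, n)
  vapply(seq_len(n), function(i) {
    gap <- abs(pi_subset(d0[i], d1[i], grid) - rho)
    grid[which.min(gap)]
  }, numeric(1))
}

#' Estimate the biomarker threshold of the responsive subpopulation
#'
#' Fits the logistic model to the pooled trial data and estimates the
#' true threshold as the grid value of `B` minimising
#' `|Pi_hat(B) - rho|`. Uncertainty is quantified by resampling the
#' fitted coefficients (as at the interim), recomputing the argmin
#' threshold for each draw, and reporting empirical quantiles of those
#' per-draw thresholds as the interval.
#'
#' @param data Pooled trial data (`quantile`, `response`).
#' @param rho Reference response rate defining the threshold.
#' @param grid Search grid of candidate thresholds; default
#'   `seq(0, 0.999, by = 0.001)`, which resolves estimates to 3 decimals.
#' @param n_draw Number of coefficient resamples for the interval; 0
#'   skips the interval (point estimate only).
#' @param coverage Interval coverage (default 0.75).
#' @param seed Optional integer seed for the resampling.
#' @return An object of class `cbatt_threshold`: `point`, `lower`,
#'   `upper`, `coverage`, `draw_estimates`, `fit` and a `degenerate`
#'   flag (when the pooled fit has no finite MLE, no estimate is
#'   available).
#' @export
estimate_threshold <- function(data, rho, grid = seq(0, 0.999, by = 0.001),
                               n_draw = 1000, coverage = 0.75, seed = NULL) {
  stopifnot(rho > 0, rho < 1, coverage > 0, coverage < 1, n_draw >= 0)
  fit <- fit_stage_model(data)
  threshold_from_fit(fit, rho, grid, n_draw, coverage, seed)
}

# Shared with the trial runner: stopped trials estimate the threshold
# from the interim (stage-1) fit rather than refitting pooled data.
threshold_from_fit <- function(fit, rho, grid = seq(0, 0.999, by = 0.001),
                               n_draw = 1000, coverage = 0.75, seed = NULL) {
  if (fit$degenerate) {
    return(structure(list(point = NA_real_, lower = NA_real_,
                          upper = NA_real_, coverage = coverage,
                          draw_estimates = numeric(0), fit = fit,
                          degenerate = TRUE),
                     class = "cbatt_threshold"))
  }
  point <- threshold_argmin(fit$coef[1], fit$coef[2], rho, grid)
  lower <- upper <- NA_real_
  draw_est <- numeric(0)
  if (n_draw > 0) {
    draws <- sample_coefficients(fit, n_draw, seed = seed)
    draw_est <- threshold_argmin(draws$draws[, 1], draws$draws[, 2], rho, grid)
    qs <- stats::quantile(draw_est, c((1 - coverage) / 2, 1 - (1 - coverage) / 2),
                          names = FALSE, type = 1)
    lower <- qs[1]; upper <- qs[2]
  }
  structure(list(point = point, lower = lower, upper = upper,
                 coverage = coverage, draw_estimates = draw_est, fit = fit,
                 degenerate = FALSE),
            class = "cbatt_threshold")
}

#' @export
print.cbatt_threshold <- function(x, ...) {
  if (x$degenerate) {
    cat("<cbatt_threshold> unavailable: degenerate model fit\n")
  } else if (is.na(x$lower)) {
    cat(sprintf("<cbatt_threshold> T_hat = %.3f (no interval requested)\n",
                x$point))
  } else {
    cat(sprintf("<cbatt_threshold> T_hat = %.3f, %d%% interval (%.3f, %.3f)\n",
                x$point, round(100 * x$coverage), x$lower, x$upper))
  }
  invisible(x)
}

#' @export
tidy.cbatt_threshold <- function(x, ...) {
  tibble::tibble(estimate = x$point, lower = x$lower, upper = x$upper,
                 coverage = x$coverage)
}
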