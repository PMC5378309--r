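# Independent oracles used to cross-check the closed-form implementations.

# Subset response rate by adaptive quadrature of the point response rate
# over (b, 1): the definition, computed without the closed form.
subset_rate_quadrature <- function(curve, b) {
  if (b >= 1) return(response_rate(curve, 1))
  val <- stats::integrate(function(u) response_rate(curve, u),
                          lower = b, upper = 1,
                          rel.tol = 1e-13, abs.tol = 1e-13)$value
  val / (1 - b)
}

# Beta-binomial upper tail by pmf ratio recursion from k = 0 upward:
#   p(0) = B(a, n + b) / B(a, b) / B(0 + 1, n - 0 + 1) / (n + 1)  -- via
# direct product form; successive terms via
#   p(k+1)/p(k) = (n - k)/(k + 1) * (k + a)/(n - k - 1 + b).
# No lchoose/lbeta calls, so the arithmetic path is independent of the
# implementation's log-scale summation.
bb_tail_recursive <- function(q, n, a, b) {
  if (q <= 0) return(1)
  if (q > n) return(0)
  p <- numeric(n + 1)
  p[1] <- prod((b + 0:(n - 1)) / (a + b + 0:(n - 1))) # P(X = 0)
  for (k in 0:(n - 1)) {
    p[k + 2] <- p[k + 1] * (n - k) / (k + 1) * (k + a) / (n - k - 1 + b)
  }
  sum(p[(q + 1):(n + 1)]) / sum(p)
}

# Beta-binomial tail as the beta mixture of binomial tails (a third,
# quadrature-based route).
bb_tail_mixture <- function(q, n, a, b) {
  if (q <= 0) return(1)
  if (q > n) return(0)
  stats::integrate(function(p) {
    stats::dbeta(p, a, b) * stats::pbinom(q - 1, n, p, lower.tail = FALSE)
  }, 0, 1, rel.tol = 1e-10)$value
}

# Reference design used throughout the operating-characteristics study.
reference_design <- function(variant = "AD1", ...) {
  cbatt_design(s1 = 50, s2 = 50, t1 = 0.5, rho = 0.4, alpha = 0.05,
               target_power = 0.8, variant = variant, ...)
}

# Draws object with prescribed coefficients (bypasses fitting) for
# deterministic rule tests.
draws_from_matrix <- function(m) {
  colnames(m) <- c("delta0", "delta1")
  structure(list(draws = m,
                 point_estimate = c(delta0 = mean(m[, 1]),
                                    delta1 = mean(m[, 2])),
                 vcov = stats::cov(m)),
            class = "cbatt_draws")
}

# Power-curve tibble with prescribed powers, for decision-rule tests.
power_curve_fixture <- function(thresholds, powers, required = 10L) {
  out <- tibble::tibble(threshold = thresholds, power = powers,
                        beta_a = NA_real_, beta_b = NA_real_)
  class(out) <- c("cbatt_power_curve", class(out))
  attr(out, "required") <- required
  out
}
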