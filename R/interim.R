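# The interim analysis: logistic fit of the stage-1 data, multivariate
# normal resampling of the coefficients, beta fits to the resampled subset
# response rates, beta-binomial predicted power over the candidate
# thresholds, and the adaptive / fixed continuation rules.

#' Fit the stage-1 logistic model
#'
#' Maximum-likelihood logistic regression of response on biomarker
#' quantile, with covariance equal to the inverse observed Fisher
#' information. Degenerate configurations (all responses identical, or
#' separation where the MLE diverges) are flagged rather than raising:
#' downstream decision rules treat them as the corresponding analytic
#' limits.
#'
#' @param data Stage data: a data frame with `quantile` and `response`.
#' @return An object of class `cbatt_fit` with elements `coef` (named
#'   `delta0`, `delta1`), `vcov`, `n`, `degenerate` (logical) and `kind`
#'   (`"ok"`, `"all_zero"`, `"all_one"`, `"separation"`).
#' @export
fit_stage_model <- function(data) {
  validate_stage_data(data)
  if (nrow(data) < 2L) {
    stop("At least 2 subjects are required to fit the stage model.",
         call. = FALSE)
  }
  y <- data$response
  if (all(y == 0) || all(y == 1)) {
    kind <- if (all(y == 0)) "all_zero" else "all_one"
    return(structure(list(coef = c(delta0 = NA_real_, delta1 = NA_real_),
                          vcov = NULL, n = nrow(data),
                          degenerate = TRUE, kind = kind),
                     class = "cbatt_fit"))
  }
  X <- cbind(1, data$quantile)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  co <- unname(fit$coefficients)
  V <- tryCatch(chol2inv(chol(crossprod(X * sqrt(fit$weights)))),
                error = function(e) NULL)
  separated <- !fit$converged || anyNA(co) || any(abs(co) > 50) ||
    is.null(V) || any(!is.finite(V))
  structure(
    list(coef = c(delta0 = co[1], delta1 = co[2]),
         vcov = if (separated) NULL else V,
         n = nrow(data),
         degenerate = separated,
         kind = if (separated) "separation" else "ok"),
    class = "cbatt_fit"
  )
}

#' @export
print.cbatt_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<cbatt_fit> degenerate (%s), n = %d\n", x$kind, x$n))
  } else {
    cat(sprintf("<cbatt_fit> delta0 = %.4g (se %.3g), delta1 = %.4g (se %.3g), n = %d\n",
                x$coef[1], sqrt(x$vcov[1, 1]), x$coef[2], sqrt(x$vcov[2, 2]), x$n))
  }
  invisible(x)
}

#' @export
tidy.cbatt_fit <- function(x, ...) {
  if (x$degenerate) {
    return(tibble::tibble(term = c("delta0", "delta1"),
                          estimate = unname(x$coef), std.error = NA_real_))
  }
  tibble::tibble(term = c("delta0", "delta1"),
                 estimate = unname(x$coef),
                 std.error = sqrt(diag(x$vcov)))
}

#' Resample model coefficients
#'
#' Draws `n_draw` coefficient pairs from the bivariate normal distribution
#' centred at the fitted coefficients with the fitted covariance — the
#' sampling distribution implied by the Fisher information. A covariance
#' that is not positive semi-definite (numerically) is repaired by
#' clipping negative eigenvalues at zero, with a message.
#'
#' @param fit A non-degenerate [fit_stage_model()] result.
#' @param n_draw Number of draws (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `cbatt_draws`: a list with `draws` (an
#'   `n_draw` x 2 matrix, columns `delta0`, `delta1`), `point_estimate`
#'   and `vcov`.
#' @export
sample_coefficients <- function(fit, n_draw = 1000, seed = NULL) {
  stopifnot(inherits(fit, "cbatt_fit"), n_draw >= 1)
  if (fit$degenerate) {
    stop("Cannot resample coefficients from a degenerate fit.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  eg <- eigen(fit$vcov, symmetric = TRUE)
  if (any(eg$values < 0)) {
    if (any(eg$values < -1e-8)) {
      message("Covariance not positive semi-definite; negative eigenvalues clipped at 0.")
    }
    eg$values <- pmax(eg$values, 0)
  }
  L <- eg$vectors %*% (t(eg$vectors) * sqrt(eg$values))
  Z <- matrix(stats::rnorm(2 * n_draw), n_draw, 2)
  draws <- Z %*% L
  draws[, 1] <- draws[, 1] + fit$coef[1]
  draws[, 2] <- draws[, 2] + fit$coef[2]
  colnames(draws) <- c("delta0", "delta1")
  structure(list(draws = draws, point_estimate = fit$coef, vcov = fit$vcov),
            class = "cbatt_draws")
}

# Upper tail P(X >= q) of the beta-binomial(n, a, b), by direct summation
# of the pmf on the log scale. Vectorised over q.
beta_binomial_tail <- function(q, n, a, b) {
  vapply(q, function(qi) {
    if (qi <= 0) return(1)
    if (qi > n) return(0)
    k <- qi:n
    sum(exp(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)))
  }, numeric(1))
}

# Vectorised engine behind predicted_power / predicted_power_curve:
# returns power and method-of-moments beta parameters for every threshold.
power_over_grid <- function(draw_mat, grid, s2, required) {
  n_draw <- nrow(draw_mat)
  k <- length(grid)
  # subset-rate draws: n_draw x k matrix, one column per candidate threshold
  v <- matrix(
    pi_subset(rep(draw_mat[, 1], times = k),
              rep(draw_mat[, 2], times = k),
              rep(grid, each = n_draw)),
    n_draw, k
  )
  v <- pmin(pmax(v, 1e-9), 1 - 1e-9)
  m <- colMeans(v)
  va <- colSums((v - rep(m, each = n_draw))^2) / max(1, n_draw - 1)
  power <- beta_a <- beta_b <- numeric(k)
  point_mass <- is.na(va) | va < 1e-12
  for (j in seq_len(k)) {
    if (point_mass[j]) {
      # degenerate draws: beta fit undefined, use the exact binomial tail
      power[j] <- stats::pbinom(required - 1, s2, m[j], lower.tail = FALSE)
      beta_a[j] <- beta_b[j] <- NA_real_
    } else {
      # sample variance can marginally exceed m(1-m); keep moments valid
      vj <- min(va[j], m[j] * (1 - m[j]) * 0.999)
      a <- m[j] * (m[j] * (1 - m[j]) / vj - 1)
      b <- a * (1 - m[j]) / m[j]
      power[j] <- beta_binomial_tail(required, s2, a, b)
      beta_a[j] <- a; beta_b[j] <- b
    }
  }
  list(power = power, beta_a = beta_a, beta_b = beta_b)
}

#' Beta-binomial predicted power at one candidate threshold
#'
#' For each resampled coefficient pair, the subset response rate at the
#' candidate stage-2 threshold is computed; a beta distribution is fitted
#' to those draws by the method of moments; and the predicted power is the
#' probability that a beta-binomial stage-2 response count reaches the
#' remaining required responses, `P(X >= required)` with
#' `X ~ BetaBinomial(s2, a, b)`.
#'
#' Draws are clamped to `[1e-9, 1 - 1e-9]` before moment fitting. When the
#' draws are (numerically) a point mass the beta fit is undefined and the
#' exact binomial tail at the mean is used instead.
#'
#' @param draws A [sample_coefficients()] result.
#' @param threshold Candidate stage-2 recruitment threshold (quantile).
#' @param s2 Stage-2 sample size.
#' @param required Remaining responses needed, `X_H - X_obs1`. Values
#'   `<= 0` give power 1; values `> s2` give power 0.
#' @return A one-row tibble with `threshold`, `power`, `beta_a`, `beta_b`.
#' @export
predicted_power <- function(draws, threshold, s2, required) {
  stopifnot(inherits(draws, "cbatt_draws"), s2 >= 1)
  check_quantile(threshold, "threshold")
  res <- power_over_grid(draws$draws, threshold, s2, required)
  tibble::tibble(threshold = threshold, power = res$power,
                 beta_a = res$beta_a, beta_b = res$beta_b)
}

#' Predicted-power curve over the candidate threshold grid
#'
#' Evaluates [predicted_power()] at every grid threshold, reusing the same
#' coefficient draws throughout so the curve reflects one coherent
#' posterior sample.
#'
#' @inheritParams predicted_power
#' @param grid Strictly increasing candidate thresholds in `[0, 1)`.
#' @return A tibble of class `cbatt_power_curve` with one row per grid
#'   threshold and columns `threshold`, `power`, `beta_a`, `beta_b`.
#' @export
predicted_power_curve <- function(draws, grid, s2, required) {
  stopifnot(inherits(draws, "cbatt_draws"), s2 >= 1)
  if (length(grid) < 1L || is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be non-empty and strictly increasing.", call. = FALSE)
  }
  res <- power_over_grid(draws$draws, grid, s2, required)
  out <- tibble::tibble(threshold = grid, power = res$power,
                        beta_a = res$beta_a, beta_b = res$beta_b)
  class(out) <- c("cbatt_power_curve", class(out))
  attr(out, "required") <- required
  attr(out, "s2") <- s2
  out
}

new_decision <- function(action, chosen_t2, rule, remaining_required,
                         diagnostics = NULL) {
  structure(list(action = action, chosen_t2 = chosen_t2, rule = rule,
                 remaining_required = remaining_required,
                 diagnostics = diagnostics),
            class = "cbatt_decision")
}

#' @export
print.cbatt_decision <- function(x, ...) {
  cat(sprintf("<cbatt_decision> %s: %s (remaining required = %d)\n",
              x$rule,
              if (x$action == "continue") sprintf("continue at t2 = %g", x$chosen_t2)
              else "stop for futility",
              x$remaining_required))
  invisible(x)
}

#' Adaptive interim decision rule
#'
#' Chooses the stage-2 threshold from a predicted-power curve. If any grid
#' threshold attains the target power, the smallest such threshold is
#' used. Otherwise AD1 stops; AD2 continues at the largest grid threshold
#' provided its predicted power strictly exceeds `gamma`, else stops; AD3
#' always continues at the largest grid threshold.
#'
#' @param curve A [predicted_power_curve()] tibble.
#' @param target_power Target power `1 - beta`.
#' @param gamma AD2 fallback bound (equals `target_power` under AD1, 0
#'   under AD3).
#' @param variant `"AD1"`, `"AD2"` or `"AD3"`.
#' @return A `cbatt_decision`.
#' @export
decide_adaptive <- function(curve, target_power, gamma,
                            variant = c("AD1", "AD2", "AD3")) {
  variant <- match.arg(variant)
  if (variant == "AD1") gamma <- target_power
  if (variant == "AD3") gamma <- 0
  required <- attr(curve, "required") %||% NA_integer_
  hit <- which(curve$power >= target_power)
  if (length(hit) > 0L) {
    return(new_decision("continue", curve$threshold[min(hit)], variant,
                        as.integer(required), curve))
  }
  k <- nrow(curve)
  if (variant == "AD3" || curve$power[k] > gamma) {
    return(new_decision("continue", curve$threshold[k], variant,
                        as.integer(required), curve))
  }
  new_decision("stop", NA_real_, variant, as.integer(required), curve)
}

#' Fixed-design interim decision rule
#'
#' FD1 ignores the biomarker at the interim and applies a beta-binomial
#' futility rule to the raw stage-1 response count: with
#' `X2 ~ BetaBinomial(s2, x_ob1, s1 - x_ob1)`, the trial stops when
#' `P(X2 >= x_h - x_ob1)` falls strictly below `fd_futility`
#' (`= 1 - beta_FD`). Boundary counts use the degenerate limits: a
#' stage with no responses gives predictive probability 0, a stage with
#' all responses gives 1 (for attainable remainders). FD2 always
#' continues.
#'
#' @param x_ob1 Stage-1 response count.
#' @param s1,s2 Stage sample sizes.
#' @param x_h Total responses required for final significance.
#' @param fd_futility Stopping bound `1 - beta_FD`.
#' @param variant `"FD1"` or `"FD2"`.
#' @return A `cbatt_decision` whose `chosen_t2` is `NA` (the fixed design
#'   keeps its threshold); `diagnostics` holds the predictive tail.
#' @export
decide_fixed <- function(x_ob1, s1, s2, x_h, fd_futility,
                         variant = c("FD1", "FD2")) {
  variant <- match.arg(variant)
  stopifnot(x_ob1 >= 0, x_ob1 <= s1)
  required <- x_h - x_ob1
  if (variant == "FD2") {
    return(new_decision("continue", NA_real_, variant, as.integer(required)))
  }
  tail <- if (required <= 0) {
    1
  } else if (x_ob1 == 0) {
    0 # limit of Beta(eps, s1): all mass at response rate 0
  } else if (x_ob1 == s1) {
    if (required <= s2) 1 else 0 # Beta(s1, eps): point mass at 1
  } else {
    beta_binomial_tail(required, s2, x_ob1, s1 - x_ob1)
  }
  action <- if (tail < fd_futility) "stop" else "continue"
  new_decision(action, NA_real_, variant, as.integer(required),
               list(predictive_tail = tail))
}

#' Run the interim analysis on stage-1 data
#'
#' Computes the remaining required responses, and applies the design's
#' interim rule: for adaptive variants the stage-1 model is fitted, its
#' coefficients resampled, the predicted-power curve evaluated over the
#' candidate grid and the adaptive rule applied; for fixed variants the
#' beta-binomial count rule is applied directly. Degenerate stage-1 fits
#' use the analytic limits: all responses 0 stops the trial (predicted
#' power 0 everywhere), while all responses 1 or a separated fit with a
#' positive trend continues at the smallest grid threshold.
#'
#' @param data Stage-1 data (`quantile`, `response`).
#' @param design A [cbatt_design()].
#' @param seed Optional integer seed for the coefficient resampling.
#' @return An object of class `cbatt_interim`: a list with `x_ob1`,
#'   `x_h`, `remaining_required`, `fit`, `power_curve` (adaptive variants)
#'   and `decision`.
#' @export
interim_analysis <- function(data, design, seed = NULL) {
  stopifnot(inherits(design, "cbatt_design"))
  validate_stage_data(data)
  x_ob1 <- sum(data$response)
  x_h <- required_responses(design$s1 + design$s2, design$rho, design$alpha)
  required <- x_h - x_ob1
  fit <- fit_stage_model(data)
  power_curve <- NULL
  if (!is_adaptive(design)) {
    decision <- decide_fixed(x_ob1, design$s1, design$s2, x_h,
                             design$fd_futility, design$variant)
  } else if (fit$degenerate) {
    message(sprintf("Degenerate stage-1 fit (%s); using the analytic limiting decision.",
                    fit$kind))
    decision <- if (fit$kind == "all_zero") {
      new_decision("stop", NA_real_, design$variant, as.integer(required))
    } else {
      new_decision("continue", design$t2_grid[1], design$variant,
                   as.integer(required))
    }
  } else {
    draws <- sample_coefficients(fit, design$n_draw, seed = seed)
    power_curve <- predicted_power_curve(draws, design$t2_grid, design$s2,
                                         required)
    decision <- decide_adaptive(power_curve, design$target_power,
                                design$gamma, design$variant)
  }
  structure(
    list(x_ob1 = x_ob1, x_h = x_h, remaining_required = as.integer(required),
         fit = fit, power_curve = power_curve, decision = decision,
         design = design, seed = seed),
    class = "cbatt_interim"
  )
}

#' @export
print.cbatt_interim <- function(x, ...) {
  cat(sprintf("<cbatt_interim> X_obs1 = %d, X_H = %d, remaining = %d\n",
              x$x_ob1, x$x_h, x$remaining_required))
  print(x$decision)
  invisible(x)
}

#' @export
tidy.cbatt_interim <- function(x, ...) {
  if (is.null(x$power_curve)) {
    return(tibble::tibble(threshold = NA_real_,
                          power = x$decision$diagnostics$predictive_tail %||% NA_real_,
                          beta_a = NA_real_, beta_b = NA_real_))
  }
  tibble::as_tibble(x$power_curve)
}

#' @export
glance.cbatt_interim <- function(x, ...) {
  tibble::tibble(
    x_ob1 = x$x_ob1, x_h = x$x_h,
    remaining_required = x$remaining_required,
    action = x$decision$action,
    chosen_t2 = x$decision$chosen_t2,
    rule = x$decision$rule,
    degenerate_fit = x$fit$degenerate
  )
}

#' Serialise an interim report to JSON
#'
#' @param x A [interim_analysis()] result.
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_interim_report <- function(x, path) {
  stopifnot(inherits(x, "cbatt_interim"))
  report <- list(
    x_ob1 = x$x_ob1, x_h = x$x_h, remaining_required = x$remaining_required,
    action = x$decision$action, chosen_t2 = x$decision$chosen_t2,
    rule = x$decision$rule, seed = x$seed,
    power_curve = if (!is.null(x$power_curve)) as.data.frame(x$power_curve)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
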