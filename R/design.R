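# Trial design specification and seed bookkeeping.

#' Two-stage trial design specification
#'
#' All fixed parameters of a two-stage enrichment trial. Five variants are
#' supported. The adaptive variants re-choose the stage-2 recruitment
#' threshold at the interim from `t2_grid` using beta-binomial predicted
#' power: AD1 stops for futility when no grid threshold reaches the target
#' power; AD2 falls back to the largest grid threshold provided its
#' predicted power exceeds `gamma`; AD3 never stops (it always falls back
#' to the largest threshold). The fixed variants keep `t1` throughout:
#' FD1 applies a beta-binomial futility rule on the raw stage-1 response
#' count and FD2 never stops.
#'
#' @param s1,s2 Stage sample sizes (positive integers).
#' @param t1 Stage-1 recruitment threshold (biomarker quantile in `[0, 1)`).
#' @param rho Reference response rate tested against, in `(0, 1)`.
#' @param alpha One-sided significance level of the final binomial exact
#'   test (default 0.05). Significance is declared when `p <= alpha`.
#' @param target_power Target (predicted) power `1 - beta` used by the
#'   adaptive interim rule (default 0.8).
#' @param gamma Minimum predicted power at the largest grid threshold for
#'   AD2 to continue. Forced to `target_power` for AD1 and 0 for AD3;
#'   required for AD2.
#' @param fd_futility Minimum predictive probability of eventual success
#'   for FD1 to continue, `1 - beta_FD` (default 0.2): FD1 stops when the
#'   beta-binomial probability of still reaching `X_H` falls strictly
#'   below this value.
#' @param t2_grid Candidate stage-2 thresholds, strictly increasing within
#'   `[0, 1)`. Default `seq(0, 0.95, by = 0.05)` (20 values). Values below
#'   `t1` are allowed: the stage-1 model is extrapolated there.
#' @param variant One of `"AD1"`, `"AD2"`, `"AD3"`, `"FD1"`, `"FD2"`.
#' @param n_draw Number of coefficient resamples used by the adaptive
#'   interim and by threshold-interval estimation (default 1000).
#' @return An object of class `cbatt_design`.
#' @examples
#' cbatt_design(s1 = 50, s2 = 50, t1 = 0.5, rho = 0.4)
#' @export
cbatt_design <- function(s1, s2, t1, rho, alpha = 0.05, target_power = 0.8,
                         gamma = NULL, fd_futility = 0.2,
                         t2_grid = seq(0, 0.95, by = 0.05),
                         variant = c("AD1", "AD2", "AD3", "FD1", "FD2"),
                         n_draw = 1000) {
  variant <- match.arg(variant)
  stopifnot(s1 >= 1, s2 >= 1, s1 == round(s1), s2 == round(s2),
            t1 >= 0, t1 < 1, rho > 0, rho < 1,
            alpha > 0, alpha <= 1, target_power > 0, target_power < 1,
            fd_futility >= 0, fd_futility <= 1, n_draw >= 1)
  if (length(t2_grid) < 1L || any(t2_grid < 0 | t2_grid >= 1) ||
      is.unsorted(t2_grid, strictly = TRUE)) {
    stop("`t2_grid` must be strictly increasing within [0, 1).", call. = FALSE)
  }
  gamma <- switch(variant,
    AD1 = target_power,
    AD3 = 0,
    AD2 = {
      if (is.null(gamma)) stop("AD2 requires `gamma`.", call. = FALSE)
      stopifnot(gamma >= 0, gamma <= target_power)
      gamma
    },
    NA_real_ # fixed designs do not use gamma
  )
  structure(
    list(s1 = as.integer(s1), s2 = as.integer(s2), t1 = t1, rho = rho,
         alpha = alpha, target_power = target_power, gamma = gamma,
         fd_futility = fd_futility, t2_grid = t2_grid, variant = variant,
         n_draw = as.integer(n_draw)),
    class = "cbatt_design"
  )
}

#' @export
print.cbatt_design <- function(x, ...) {
  cat(sprintf("<cbatt_design> %s: S1 = %d, S2 = %d, t1 = %g, rho = %g, alpha = %g\n",
              x$variant, x$s1, x$s2, x$t1, x$rho, x$alpha))
  if (startsWith(x$variant, "AD")) {
    cat(sprintf("  target power = %g, gamma = %g, %d candidate t2 in [%g, %g], %d draws\n",
                x$target_power, x$gamma, length(x$t2_grid),
                min(x$t2_grid), max(x$t2_grid), x$n_draw))
  } else {
    cat(sprintf("  fixed threshold; futility bound 1 - beta_FD = %g (%s)\n",
                x$fd_futility,
                if (x$variant == "FD1") "stopping enabled" else "no stopping"))
  }
  invisible(x)
}

is_adaptive <- function(design) startsWith(design$variant, "AD")

# Derive a reproducible child seed from a parent seed. Arithmetic stays
# within double precision (< 2^53) and the result within R's integer range.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 1103 * i) %% 2147483629)
}

# Resolve a possibly-NULL seed: draw one from the current RNG state so the
# call is reproducible whenever the caller has set a seed.
resolve_seed <- function(seed) {
  if (is.null(seed)) sample.int(2147483629L, 1L) else as.integer(seed)
}
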