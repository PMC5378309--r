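# Simulation scenarios: a true response curve plus the reference rate the
# trial tests against, with the implied true threshold bookkeeping.

#' Simulation scenario
#'
#' Bundles a true biomarker-response curve with the reference ("null")
#' response rate `rho` the trial tests against. The true threshold `T` is
#' the smallest quantile whose subset response rate reaches `rho`; the
#' hypothesis threshold is the analogue for the required response rate
#' `R_H = X_H / S`. Both are derived from the curve on construction (and
#' are `NA` when the curve never attains the rate).
#'
#' @param curve A [logistic_curve()]: the true response model.
#' @param rho Reference response rate in `(0, 1)`.
#' @param r_h Optional required response rate `X_H / S`; when supplied the
#'   hypothesis threshold is recorded too.
#' @return An object of class `cbatt_scenario`.
#' @export
cbatt_scenario <- function(curve, rho, r_h = NULL) {
  stopifnot(inherits(curve, "cbatt_curve"), rho > 0, rho < 1)
  true_threshold <- if (curve$delta1 < 1e-8) {
    # constant-rate curve: T = 0 when the rate exceeds rho, else undefined
    if (stats::plogis(curve$delta0) > rho) 0 else NA_real_
  } else {
    threshold_for_rate(curve, rho)
  }
  hypothesis_threshold <- if (!is.null(r_h) && curve$delta1 >= 1e-8) {
    threshold_for_rate(curve, r_h)
  } else {
    NA_real_
  }
  structure(
    list(curve = curve, rho = rho,
         true_threshold = true_threshold,
         hypothesis_threshold = hypothesis_threshold),
    class = "cbatt_scenario"
  )
}

#' @export
print.cbatt_scenario <- function(x, ...) {
  cat(sprintf("<cbatt_scenario> delta0 = %.4g, delta1 = %.4g, rho = %g\n",
              x$curve$delta0, x$curve$delta1, x$rho))
  cat(sprintf("  true threshold T = %s, hypothesis threshold = %s\n",
              format(round(x$true_threshold, 4)),
              format(round(x$hypothesis_threshold, 4))))
  invisible(x)
}

#' Build a scenario from a slope and a threshold anchor
#'
#' Reconstructs the simulation scenarios of the operating-characteristics
#' study: given a slope and either a true threshold (anchored at the
#' reference rate `rho`) or a hypothesis threshold (anchored at the
#' required rate `r_h`), the intercept is calibrated so the subset
#' response rate passes through the anchor.
#'
#' @param delta1 Log odds ratio per unit quantile (non-negative).
#' @param anchor `"T"` to anchor `Pi(anchor_b) = rho`, `"T_H"` to anchor
#'   `Pi(anchor_b) = r_h`.
#' @param anchor_b The threshold quantile being prescribed.
#' @param rho Reference response rate (default 0.4).
#' @param r_h Required response rate `X_H / S` (default 0.49, the value for
#'   a 100-subject trial at `rho = 0.4`, `alpha = 0.05`).
#' @return A `cbatt_scenario`.
#' @examples
#' sc <- scenario_from_anchor(6, "T", 0.5)
#' round(subset_rate(sc$curve, c(0, 0.95)), 2)
#' @export
scenario_from_anchor <- function(delta1, anchor = c("T", "T_H"), anchor_b,
                                 rho = 0.4, r_h = 0.49) {
  anchor <- match.arg(anchor)
  anchor_rate <- if (anchor == "T") rho else r_h
  if (delta1 < 1e-8) {
    # degenerate flat curve: the anchor rate holds everywhere
    return(constant_scenario(anchor_rate, rho))
  }
  curve <- calibrate_intercept(delta1, anchor_b, anchor_rate)
  cbatt_scenario(curve, rho, r_h = r_h)
}

#' Scenario with a constant response rate (no biomarker effect)
#'
#' @param rate The common response probability for every subject.
#' @param rho Reference response rate.
#' @return A `cbatt_scenario` whose curve has slope 0.
#' @export
constant_scenario <- function(rate, rho = 0.4) {
  stopifnot(rate > 0, rate < 1)
  cbatt_scenario(logistic_curve(stats::qlogis(rate), 0), rho)
}
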