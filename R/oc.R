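# Operating characteristics: Monte-Carlo batches of simulated trials, the
# exact enumeration available for constant-rate fixed designs, and
# screening-burden comparisons between designs.

#' Monte-Carlo operating characteristics of a design
#'
#' Runs `n_iter` independent trials under the scenario and aggregates the
#' design's operating characteristics: the proportion of all trials with
#' a significant final test (stopped trials count as failures), the
#' proportion significant among completed trials, the futility stopping
#' rate, mean expected screening burden, the chosen stage-2 thresholds,
#' and the bias of the threshold estimate (`T_hat - T`, summarised by
#' median and interquartile range; stopped trials contribute estimates
#' from their interim fit). Bias summaries are `NA` for scenarios without
#' a defined true threshold or when estimation is disabled.
#'
#' @param design A [cbatt_design()].
#' @param scenario A [cbatt_scenario()].
#' @param n_iter Number of simulated trials.
#' @param seed Integer master seed; per-trial seeds are derived from it.
#' @param estimate Estimate the threshold in every trial (default `TRUE`;
#'   disable for speed when only error rates are needed).
#' @return An object of class `cbatt_oc`. [glance()] gives the one-row
#'   summary, [tidy()] the per-trial results.
#' @export
simulate_oc <- function(design, scenario, n_iter, seed = NULL,
                        estimate = TRUE) {
  stopifnot(n_iter >= 1)
  seed <- resolve_seed(seed)
  set.seed(seed)
  trial_seeds <- sample.int(2147483629L, n_iter)
  trials <- purrr::map_dfr(trial_seeds, function(s) {
    glance(run_trial(design, scenario, seed = s, estimate = estimate))
  })
  completed <- !trials$stopped_at_interim
  t_true <- scenario$true_threshold
  bias <- if (estimate && !is.na(t_true)) trials$t_hat - t_true else NULL
  structure(
    list(
      design = design, scenario = scenario, seed = seed, n_iter = n_iter,
      trials = trials,
      prop_significant_overall = mean(trials$significant),
      prop_significant_completed = if (any(completed)) {
        mean(trials$significant[completed])
      } else {
        NA_real_
      },
      stopping_rate = mean(trials$stopped_at_interim),
      mean_screened = mean(trials$screened_expected),
      mean_screened_completed = if (any(completed)) {
        mean(trials$screened_expected[completed])
      } else {
        NA_real_
      },
      median_t2 = if (any(completed)) {
        stats::median(trials$chosen_t2[completed], na.rm = TRUE)
      } else {
        NA_real_
      },
      median_bias = if (is.null(bias)) NA_real_
                    else stats::median(bias, na.rm = TRUE),
      bias_iqr = if (is.null(bias)) NA_real_ else stats::IQR(bias, na.rm = TRUE),
      mean_bias = if (is.null(bias)) NA_real_ else mean(bias, na.rm = TRUE)
    ),
    class = "cbatt_oc"
  )
}

#' @export
print.cbatt_oc <- function(x, ...) {
  cat(sprintf("<cbatt_oc> %s, %d iterations (seed %d)\n",
              x$design$variant, x$n_iter, x$seed))
  cat(sprintf("  significant: %.3f overall, %.3f among completed; stopping rate %.3f\n",
              x$prop_significant_overall, x$prop_significant_completed,
              x$stopping_rate))
  cat(sprintf("  mean screens %.1f; median t2 %s; median bias %s (IQR %s)\n",
              x$mean_screened, format(round(x$median_t2, 3)),
              format(round(x$median_bias, 3)), format(round(x$bias_iqr, 3))))
  invisible(x)
}

#' @rdname simulate_oc
#' @param x A `cbatt_oc` object.
#' @param ... Unused.
#' @export
glance.cbatt_oc <- function(x, ...) {
  tibble::tibble(
    variant = x$design$variant,
    n_iter = x$n_iter,
    prop_significant_overall = x$prop_significant_overall,
    prop_significant_completed = x$prop_significant_completed,
    stopping_rate = x$stopping_rate,
    mean_screened = x$mean_screened,
    median_t2 = x$median_t2,
    median_bias = x$median_bias,
    bias_iqr = x$bias_iqr
  )
}

#' @rdname simulate_oc
#' @export
tidy.cbatt_oc <- function(x, ...) {
  x$trials
}

#' Exact operating characteristics for constant-rate fixed designs
#'
#' When the response rate is constant (no biomarker effect) and the
#' recruitment threshold is fixed, the stage-1 response count is
#' `Binomial(s1, pi)` and the stopping indicator and final significance
#' probability can be enumerated exactly — no Monte Carlo.
#'
#' @param design A fixed-variant (`FD1`/`FD2`) [cbatt_design()].
#' @param pi The constant response probability.
#' @return A one-row tibble: `stopping_rate`, `power_overall`,
#'   `power_completed`.
#' @export
exact_oc_constant_rate <- function(design, pi) {
  stopifnot(inherits(design, "cbatt_design"), pi >= 0, pi <= 1)
  if (is_adaptive(design)) {
    stop("Exact enumeration is available for fixed-threshold designs only.",
         call. = FALSE)
  }
  x_h <- required_responses(design$s1 + design$s2, design$rho, design$alpha)
  x1 <- 0:design$s1
  pr1 <- stats::dbinom(x1, design$s1, pi)
  stop_ind <- vapply(x1, function(k) {
    decide_fixed(k, design$s1, design$s2, x_h, design$fd_futility,
                 design$variant)$action == "stop"
  }, logical(1))
  p_sig <- stats::pbinom(x_h - x1 - 1, design$s2, pi, lower.tail = FALSE)
  stopping_rate <- sum(pr1[stop_ind])
  power_overall <- sum(pr1 * (!stop_ind) * p_sig)
  power_completed <- if (stopping_rate < 1) {
    power_overall / (1 - stopping_rate)
  } else {
    NA_real_
  }
  tibble::tibble(stopping_rate = stopping_rate,
                 power_overall = power_overall,
                 power_completed = power_completed)
}

#' Screening-burden ratio between two designs
#'
#' Ratio of the mean expected number of biomarker screens between an
#' adaptive and a fixed design run on matched scenarios, overall and
#' restricted to completed trials. When the fixed design completes no
#' trials, the completed-trial denominator falls back to the theoretical
#' screening burden of a completed fixed trial,
#' `s1 / (1 - t1) + s2 / (1 - t1)`.
#'
#' @param oc_adaptive,oc_fixed [simulate_oc()] results on the same
#'   scenario.
#' @return A one-row tibble with `overall_ratio` and `completed_ratio`.
#' @export
screening_ratio <- function(oc_adaptive, oc_fixed) {
  stopifnot(inherits(oc_adaptive, "cbatt_oc"), inherits(oc_fixed, "cbatt_oc"))
  overall <- oc_adaptive$mean_screened / oc_fixed$mean_screened
  fixed_completed <- oc_fixed$mean_screened_completed
  if (is.na(fixed_completed)) {
    d <- oc_fixed$design
    fixed_completed <- d$s1 / (1 - d$t1) + d$s2 / (1 - d$t1)
  }
  completed <- if (is.na(oc_adaptive$mean_screened_completed)) {
    NA_real_
  } else {
    oc_adaptive$mean_screened_completed / fixed_completed
  }
  tibble::tibble(overall_ratio = overall, completed_ratio = completed)
}

#' Tabulate operating characteristics across scenarios
#'
#' Convenience wrapper reproducing the shape of an
#' operating-characteristics table: one [simulate_oc()] row per scenario.
#'
#' @param design A [cbatt_design()].
#' @param scenarios A list of [cbatt_scenario()] objects.
#' @param n_iter Trials per scenario.
#' @param seed Master seed; each scenario gets a derived seed.
#' @param estimate Estimate thresholds per trial (default `TRUE`).
#' @return A tibble with one row per scenario.
#' @export
oc_table <- function(design, scenarios, n_iter, seed = NULL, estimate = TRUE) {
  seed <- resolve_seed(seed)
  purrr::imap_dfr(scenarios, function(sc, i) {
    oc <- simulate_oc(design, sc, n_iter, seed = child_seed(seed, i),
                      estimate = estimate)
    dplyr::bind_cols(
      tibble::tibble(delta1 = sc$curve$delta1,
                     true_threshold = sc$true_threshold,
                     pi0 = subset_rate(sc$curve, 0),
                     pi95 = subset_rate(sc$curve, 0.95)),
      glance(oc)
    )
  })
}
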