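# One complete simulated trial: stage 1, interim, optional stage 2,
# final exact test and threshold estimation, screening accounting.

#' Simulate one complete two-stage trial
#'
#' Runs a full trial under the given design and true scenario: stage-1
#' recruitment above `t1`, the interim rule (adaptive threshold choice or
#' fixed-design futility check), stage-2 recruitment above the chosen
#' threshold when the trial continues, the binomial exact test on all
#' pooled subjects, and estimation of the biomarker threshold. Stopped
#' trials estimate the threshold from the interim (stage-1) model fit.
#'
#' The expected screening burden is recorded analytically: recruiting `n`
#' subjects above quantile threshold `t` requires on average `n / (1 - t)`
#' biomarker screens.
#'
#' A master seed drives three independent substreams (stage-1 data,
#' interim coefficient draws, stage-2 data), so the whole trial is
#' bit-reproducible and changing `n_draw` does not perturb recruitment.
#'
#' @param design A [cbatt_design()].
#' @param scenario A [cbatt_scenario()] describing the truth.
#' @param seed Integer master seed; drawn from the session RNG when `NULL`.
#' @param estimate Estimate the biomarker threshold (default `TRUE`).
#' @param ci_draws Coefficient resamples for the threshold interval
#'   (default 0: point estimate only, as used in batch simulation).
#' @param coverage Interval coverage when `ci_draws > 0`.
#' @return An object of class `cbatt_trial`. Use [glance()] for a one-row
#'   tibble summary.
#' @examples
#' design <- cbatt_design(s1 = 50, s2 = 50, t1 = 0.5, rho = 0.4)
#' sc <- scenario_from_anchor(6, "T", 0.5)
#' glance(run_trial(design, sc, seed = 1))
#' @export
run_trial <- function(design, scenario, seed = NULL, estimate = TRUE,
                      ci_draws = 0, coverage = 0.75) {
  stopifnot(inherits(design, "cbatt_design"),
            inherits(scenario, "cbatt_scenario"))
  seed <- resolve_seed(seed)
  curve <- scenario$curve

  stage1 <- generate_stage(design$s1, design$t1, curve, stage = 1L,
                           seed = child_seed(seed, 1L))
  interim <- interim_analysis(stage1, design, seed = child_seed(seed, 2L))
  stopped <- interim$decision$action == "stop"
  t2 <- if (stopped) NA_real_
        else if (is_adaptive(design)) interim$decision$chosen_t2
        else design$t1 # fixed designs keep the stage-1 threshold

  screened <- design$s1 / (1 - design$t1)
  x_ob2 <- NA_integer_
  p_value <- NA_real_
  significant <- FALSE
  pooled <- stage1
  if (!stopped) {
    stage2 <- generate_stage(design$s2, t2, curve, stage = 2L,
                             seed = child_seed(seed, 3L))
    pooled <- dplyr::bind_rows(stage1, stage2)
    x_ob2 <- sum(stage2$response)
    x_ob <- interim$x_ob1 + x_ob2
    p_value <- exact_test(x_ob, design$s1 + design$s2, design$rho)
    significant <- p_value <= design$alpha
    screened <- screened + design$s2 / (1 - t2)
  }

  threshold <- NULL
  if (estimate) {
    fit <- if (stopped) interim$fit else fit_stage_model(pooled)
    threshold <- threshold_from_fit(fit, design$rho, n_draw = ci_draws,
                                    coverage = coverage,
                                    seed = child_seed(seed, 4L))
  }

  structure(
    list(design = design, scenario = scenario, seed = seed,
         stopped_at_interim = stopped, chosen_t2 = t2,
         x_ob1 = interim$x_ob1, x_ob2 = x_ob2,
         x_ob = if (stopped) interim$x_ob1 else interim$x_ob1 + x_ob2,
         p_value = p_value, significant = significant,
         interim = interim, data = pooled,
         threshold_estimate = threshold,
         screened_expected = screened),
    class = "cbatt_trial"
  )
}

#' @export
print.cbatt_trial <- function(x, ...) {
  cat(sprintf("<cbatt_trial> %s, seed %d\n", x$design$variant, x$seed))
  if (x$stopped_at_interim) {
    cat(sprintf("  stopped at interim: X_obs1 = %d of %d required\n",
                x$x_ob1, x$interim$x_h))
  } else {
    cat(sprintf("  completed at t2 = %g: X_obs = %d/%d, p = %.3g (%ssignificant)\n",
                x$chosen_t2, x$x_ob, x$design$s1 + x$design$s2, x$p_value,
                if (x$significant) "" else "not "))
  }
  if (!is.null(x$threshold_estimate)) print(x$threshold_estimate)
  invisible(x)
}

#' @rdname run_trial
#' @param x A `cbatt_trial`.
#' @param ... Unused.
#' @export
glance.cbatt_trial <- function(x, ...) {
  tibble::new_tibble(list(
    variant = x$design$variant,
    seed = x$seed,
    stopped_at_interim = x$stopped_at_interim,
    chosen_t2 = x$chosen_t2,
    x_ob1 = x$x_ob1,
    x_ob2 = x$x_ob2,
    x_ob = x$x_ob,
    p_value = x$p_value,
    significant = x$significant,
    t_hat = if (is.null(x$threshold_estimate)) NA_real_
            else x$threshold_estimate$point,
    screened_expected = x$screened_expected
  ), nrow = 1L)
}
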