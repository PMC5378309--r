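# Operating characteristics: Monte-Carlo batches, exact enumeration for
# constant-rate fixed designs, scenario construction, screening ratios.

test_that("the overall/completed/stopping accounting identity holds", {
  oc <- simulate_oc(reference_design(), scenario_from_anchor(6, "T", 0.5),
                    n_iter = 150, seed = 3, estimate = FALSE)
  expect_equal(oc$prop_significant_overall,
               oc$prop_significant_completed * (1 - oc$stopping_rate),
               tolerance = 1e-12)
  expect_identical(nrow(oc$trials), 150L)
  expect_identical(simulate_oc(reference_design(),
                               scenario_from_anchor(6, "T", 0.5),
                               n_iter = 150, seed = 3,
                               estimate = FALSE)$trials,
                   oc$trials)
})

test_that("exact constant-rate enumeration matches simulation and limits", {
  des <- reference_design("FD1")
  # no responses possible: every trial stops, no power
  ex <- exact_oc_constant_rate(des, 0)
  expect_equal(ex$stopping_rate, 1)
  expect_equal(ex$power_overall, 0)
  # self-consistency with the Monte-Carlo route
  for (p in c(0.35, 0.5)) {
    ex <- exact_oc_constant_rate(des, p)
    oc <- simulate_oc(des, constant_scenario(p), n_iter = 4000, seed = 5,
                      estimate = FALSE)
    se_stop <- sqrt(ex$stopping_rate * (1 - ex$stopping_rate) / 4000)
    se_pow <- sqrt(max(ex$power_overall * (1 - ex$power_overall), 1e-6) / 4000)
    expect_lt(abs(oc$stopping_rate - ex$stopping_rate), 4 * se_stop + 1e-9)
    expect_lt(abs(oc$prop_significant_overall - ex$power_overall),
              4 * se_pow + 1e-9)
  }
  expect_error(exact_oc_constant_rate(reference_design("AD1"), 0.4),
               "fixed-threshold")
})

test_that("scenario construction reproduces the anchored curves", {
  sc <- scenario_from_anchor(9, "T", 0.4)
  expect_equal(round(subset_rate(sc$curve, 0), 2), 0.24)
  expect_equal(round(subset_rate(sc$curve, 0.95), 2), 0.86)
  expect_equal(round(sc$hypothesis_threshold, 2), 0.53)

  sc <- scenario_from_anchor(6, "T_H", 0.5)
  expect_equal(round(subset_rate(sc$curve, 0), 2), 0.28)
  expect_equal(round(subset_rate(sc$curve, 0.95), 2), 0.79)
  expect_lt(abs(sc$true_threshold - 0.34), 0.005)

  # flat-slope anchor degenerates to a constant-rate scenario
  sc <- scenario_from_anchor(0, "T", 0.5, rho = 0.4)
  expect_equal(sc$curve$delta1, 0)
  expect_equal(response_rate(sc$curve, 0.1), 0.4)
})

test_that("stopping rate rises with the true threshold", {
  des <- reference_design()
  stops <- vapply(c(0.2, 0.5, 0.8), function(tt) {
    simulate_oc(des, scenario_from_anchor(6, "T", tt), n_iter = 250,
                seed = 19, estimate = FALSE)$stopping_rate
  }, numeric(1))
  expect_true(all(diff(stops) > 0))
})

test_that("screening ratios compare mean screens with the completed fallback", {
  sc <- scenario_from_anchor(6, "T", 0.5)
  oc_ad <- simulate_oc(reference_design(), sc, 100, seed = 2, estimate = FALSE)
  expect_equal(screening_ratio(oc_ad, oc_ad)$overall_ratio, 1)
  # a fixed design completing no trials: denominator falls back to the
  # theoretical completed-trial screening burden 200
  oc_fd <- simulate_oc(reference_design("FD1"), sc, 50, seed = 4,
                       estimate = FALSE)
  oc_fd$mean_screened_completed <- NA_real_
  r <- screening_ratio(oc_ad, oc_fd)
  expect_equal(r$completed_ratio, oc_ad$mean_screened_completed / 200)
})

test_that("oc_table assembles one summary row per scenario", {
  scs <- list(scenario_from_anchor(6, "T", 0.5), constant_scenario(0.5))
  tab <- oc_table(reference_design(), scs, n_iter = 40, seed = 8,
                  estimate = FALSE)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("delta1", "true_threshold", "pi0",
                    "prop_significant_overall") %in% names(tab)))
})
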