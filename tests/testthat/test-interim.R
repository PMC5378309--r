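# Interim analysis: model fit, coefficient resampling, beta-binomial
# predicted power, and the continuation rules.

test_that("stage-1 fit recovers the generating coefficients at large n", {
  data <- generate_stage(20000, 0, logistic_curve(-3, 6), seed = 101)
  fit <- fit_stage_model(data)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$coef["delta0"] + 3), 0.15)
  expect_lt(abs(fit$coef["delta1"] - 6), 0.15)
  expect_equal(dim(fit$vcov), c(2L, 2L))
})

test_that("degenerate stage-1 configurations are flagged, not fitted", {
  d <- tibble::tibble(quantile = c(0.5, 0.6, 0.7), response = c(0, 0, 0))
  expect_identical(fit_stage_model(d)$kind, "all_zero")
  d$response <- c(1, 1, 1)
  expect_identical(fit_stage_model(d)$kind, "all_one")
  # perfect separation: responder iff quantile above a cut
  d <- tibble::tibble(quantile = c(0.5, 0.9), response = c(0, 1))
  fit <- fit_stage_model(d)
  expect_true(fit$degenerate)
  expect_identical(fit$kind, "separation")
  expect_error(fit_stage_model(d[1, ]), "At least 2")
})

test_that("coefficient resampling is centred, seeded, and degenerate-safe", {
  data <- generate_stage(400, 0.5, logistic_curve(-3, 6), seed = 7)
  fit <- fit_stage_model(data)
  draws <- sample_coefficients(fit, 1e5, seed = 1)
  se <- sqrt(diag(fit$vcov) / 1e5)
  expect_lt(abs(mean(draws$draws[, 1]) - fit$coef[1]), 4 * se[1])
  expect_lt(abs(mean(draws$draws[, 2]) - fit$coef[2]), 4 * se[2])
  # determinism
  again <- sample_coefficients(fit, 1e5, seed = 1)
  expect_identical(draws$draws, again$draws)
  # zero covariance: every draw equals the point estimate
  fit0 <- fit
  fit0$vcov <- matrix(0, 2, 2)
  d0 <- sample_coefficients(fit0, 50, seed = 2)
  expect_true(all(d0$draws[, 1] == fit$coef[1]))
  expect_true(all(d0$draws[, 2] == fit$coef[2]))
  # indefinite covariance is repaired by clipping
  fitn <- fit
  fitn$vcov <- matrix(c(1, 0, 0, -0.5), 2, 2)
  expect_message(dn <- sample_coefficients(fitn, 1000, seed = 3), "clipped")
  expect_equal(sd(dn$draws[, 2]), 0, tolerance = 1e-12)
})

test_that("beta-binomial tail matches independent recursion and mixture oracles", {
  cases <- list(c(25, 50, 3.2, 4.8), c(1, 50, 0.5, 0.5), c(50, 50, 10, 2),
                c(23, 50, 26, 24), c(10, 30, 1, 1))
  for (cs in cases) {
    got <- cbatt:::beta_binomial_tail(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got, bb_tail_recursive(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
    expect_equal(got, bb_tail_mixture(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-7)
  }
})

test_that("predicted power handles trivial and degenerate cases", {
  m <- matrix(rep(c(0, 0), each = 400), ncol = 2) # all draws pi = 0.5 flat
  draws <- draws_from_matrix(m)
  expect_equal(predicted_power(draws, 0.4, 50, 0)$power, 1)
  expect_equal(predicted_power(draws, 0.4, 50, 51)$power, 0)
  # point-mass draws: power equals the exact binomial tail at the mean
  got <- predicted_power(draws, 0.4, 50, 25)
  expect_equal(got$power, pbinom(24, 50, 0.5, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_true(is.na(got$beta_a))
})

test_that("predicted power decreases in the required count", {
  data <- generate_stage(50, 0.5, logistic_curve(-3, 6), seed = 9)
  draws <- sample_coefficients(fit_stage_model(data), 500, seed = 2)
  pows <- vapply(0:51, function(r) predicted_power(draws, 0.5, 50, r)$power,
                 numeric(1))
  expect_true(all(diff(pows) <= 1e-12))
  expect_equal(pows[1], 1)
  expect_equal(pows[52], 0)
})

test_that("the power curve shares draws and is monotone for positive slopes", {
  set.seed(13)
  m <- cbind(rnorm(300, -3, 0.3), rnorm(300, 6, 0.5)) # all slopes positive
  draws <- draws_from_matrix(m)
  grid <- seq(0, 0.95, by = 0.05)
  curve <- predicted_power_curve(draws, grid, 50, 30)
  expect_s3_class(curve, "cbatt_power_curve")
  expect_equal(nrow(curve), 20L)
  expect_true(all(diff(curve$power) >= -1e-12))
  # single-point grid reduces to predicted_power
  one <- predicted_power(draws, grid[8], 50, 30)
  expect_equal(curve$power[8], one$power)
  # required = 0 gives power 1 everywhere
  expect_true(all(predicted_power_curve(draws, grid, 50, 0)$power == 1))
})

test_that("adaptive decision rules follow their variant definitions", {
  grid <- c(0, 0.05, 0.10, 0.15)
  pc <- power_curve_fixture(grid, c(0.6, 0.75, 0.81, 0.9))
  d <- decide_adaptive(pc, 0.8, 0.8, "AD1")
  expect_identical(d$action, "continue")
  expect_equal(d$chosen_t2, 0.10) # smallest threshold reaching the target

  low <- power_curve_fixture(grid, c(0.2, 0.3, 0.4, 0.55))
  expect_identical(decide_adaptive(low, 0.8, 0.8, "AD1")$action, "stop")
  d2 <- decide_adaptive(low, 0.8, 0.5, "AD2")
  expect_identical(d2$action, "continue")
  expect_equal(d2$chosen_t2, 0.15) # falls back to the largest threshold
  expect_identical(decide_adaptive(
    power_curve_fixture(grid, c(0.2, 0.3, 0.4, 0.45)), 0.8, 0.5, "AD2")$action,
    "stop")
  d3 <- decide_adaptive(power_curve_fixture(grid, rep(0, 4)), 0.8, 0, "AD3")
  expect_identical(d3$action, "continue") # AD3 never stops
  expect_equal(d3$chosen_t2, 0.15)
})

test_that("fixed-design rule matches the beta-binomial tail with observed counts", {
  # already at the required total: predictive probability 1, continue
  expect_identical(decide_fixed(49, 50, 50, 49, 0.2, "FD1")$action, "continue")
  # no stage-1 responses: degenerate limit with tail 0, stop
  d <- decide_fixed(0, 50, 50, 49, 0.2, "FD1")
  expect_identical(d$action, "stop")
  expect_equal(d$diagnostics$predictive_tail, 0)
  # tail agrees with the independent recursion
  d <- decide_fixed(26, 50, 50, 49, 0.2, "FD1")
  expect_equal(d$diagnostics$predictive_tail,
               bb_tail_recursive(49 - 26, 50, 26, 50 - 26), tolerance = 1e-12)
  # FD2 never stops
  expect_identical(decide_fixed(0, 50, 50, 49, 0.2, "FD2")$action, "continue")
})

test_that("interim analysis is reproducible and serialisable", {
  design <- reference_design()
  data <- generate_stage(50, 0.5, logistic_curve(-3, 6), seed = 17)
  a <- interim_analysis(data, design, seed = 5)
  b <- interim_analysis(data, design, seed = 5)
  expect_identical(a$power_curve, b$power_curve)
  expect_identical(a$decision$chosen_t2, b$decision$chosen_t2)
  expect_equal(a$x_h, 49L)
  path <- withr::local_tempfile(fileext = ".json")
  write_interim_report(a, path)
  rep <- jsonlite::read_json(path)
  expect_identical(rep$action, a$decision$action)
  expect_equal(length(rep$power_curve), nrow(a$power_curve))
})

test_that("degenerate stage-1 data drive the limiting interim decisions", {
  design <- reference_design()
  all0 <- tibble::tibble(quantile = runif(50, 0.5, 1), response = rep(0, 50))
  expect_message(i0 <- interim_analysis(all0, design), "Degenerate")
  expect_identical(i0$decision$action, "stop")
  all1 <- tibble::tibble(quantile = runif(50, 0.5, 1), response = rep(1, 50))
  expect_message(i1 <- interim_analysis(all1, design), "Degenerate")
  expect_identical(i1$decision$action, "continue")
  expect_equal(i1$decision$chosen_t2, design$t2_grid[1])
})
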