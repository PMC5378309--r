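# The biomarker-response model on the quantile scale.

test_that("point response rate matches the logistic closed form", {
  expect_equal(response_rate(logistic_curve(0, 0), 0.7), 0.5)
  expect_equal(response_rate(logistic_curve(-2, 0), 0.3), 1 / (1 + exp(2)))
  # strictly increasing in b for positive slope
  r <- response_rate(logistic_curve(0, 6), c(0, 0.25, 0.5, 0.75, 1))
  expect_true(all(diff(r) > 0))
  # overflow-safe at extreme linear predictors
  expect_equal(response_rate(logistic_curve(800, 0), 0.5), 1)
  expect_equal(response_rate(logistic_curve(-800, 0), 0.5), 0)
})

test_that("curve construction rejects non-finite coefficients", {
  expect_error(logistic_curve(Inf, 1), "finite")
  expect_error(logistic_curve(0, NA), "finite")
})

test_that("subset rate agrees with its quadrature definition", {
  # closed form vs direct integration of pi over (b, 1)
  expect_equal(subset_rate(logistic_curve(-1, 4), 0.3),
               subset_rate_quadrature(logistic_curve(-1, 4), 0.3),
               tolerance = 1e-10)
  set.seed(11)
  for (i in 1:100) {
    curve <- logistic_curve(stats::runif(1, -6, 2), stats::runif(1, 0, 12))
    b <- stats::runif(1)
    expect_equal(subset_rate(curve, b), subset_rate_quadrature(curve, b),
                 tolerance = 1e-10)
  }
})

test_that("subset rate limits: flat curves, b = 1, Pi(0) as full average", {
  expect_equal(subset_rate(logistic_curve(-0.7, 0), 0.42), plogis(-0.7))
  curve <- logistic_curve(-2, 5)
  expect_equal(subset_rate(curve, 1), response_rate(curve, 1))
  expect_equal(subset_rate(curve, 0),
               integrate(function(u) response_rate(curve, u), 0, 1,
                         rel.tol = 1e-12)$value,
               tolerance = 1e-10)
})

test_that("subset rate is continuous across the small-slope branch switch", {
  # the evaluation switches branches where delta1 * (1 - b) crosses 1e-4
  for (b in c(0, 0.3, 0.9)) {
    eps <- 1e-4 / (1 - b)
    expect_equal(subset_rate(logistic_curve(-0.5, eps * (1 - 1e-9)), b),
                 subset_rate(logistic_curve(-0.5, eps * (1 + 1e-9)), b),
                 tolerance = 1e-8)
  }
})

test_that("subset rate dominates the point rate and increases with b", {
  set.seed(21)
  for (i in 1:20) {
    curve <- logistic_curve(stats::runif(1, -5, 1), stats::runif(1, 0.5, 10))
    b <- seq(0, 1, by = 0.05)
    pi_b <- response_rate(curve, b)
    Pi_b <- subset_rate(curve, b)
    expect_true(all(diff(Pi_b) > 0))
    expect_true(all(Pi_b >= pi_b - 1e-12))
    expect_true(all(Pi_b <= response_rate(curve, 1) + 1e-12))
  }
})

test_that("intercept calibration hits its anchor and reproduces known scenarios", {
  curve <- calibrate_intercept(3, 0.8, 0.4)
  expect_equal(subset_rate(curve, 0.8), 0.4, tolerance = 1e-9)
  expect_equal(round(subset_rate(curve, 0), 2), 0.20)
  expect_equal(round(subset_rate(curve, 0.95), 2), 0.45)

  # slope 6 anchored at Pi(0.6) = 0.4: the quantile reaching a subset
  # rate of 0.49 is 0.74
  curve <- calibrate_intercept(6, 0.6, 0.4)
  expect_equal(round(threshold_for_rate(curve, 0.49), 2), 0.74)

  # flat curve: intercept is the logit of the anchor rate, exactly
  expect_identical(calibrate_intercept(0, 0.5, 0.4)$delta0, qlogis(0.4))
})

test_that("calibration round-trips across slopes and anchors", {
  set.seed(31)
  for (i in 1:25) {
    d1 <- stats::runif(1, 0, 12)
    ab <- stats::runif(1, 0, 0.95)
    ar <- stats::runif(1, 0.05, 0.9)
    curve <- calibrate_intercept(d1, ab, ar)
    expect_equal(subset_rate(curve, ab), ar, tolerance = 1e-9)
  }
})

test_that("two-anchor null calibration pins both subset rates", {
  curve <- calibrate_null_curve(0.39, 0.399, at = 0.95)
  expect_equal(subset_rate(curve, 0), 0.39, tolerance = 1e-8)
  expect_equal(subset_rate(curve, 0.95), 0.399, tolerance = 1e-8)
  expect_true(subset_rate(curve, 0.999) < 0.4)
})

test_that("quantile transform follows the rank/n convention and is monotone", {
  ref <- 1:100
  expect_equal(quantile_transform(50, ref), 0.50)
  expect_equal(quantile_transform(max(ref), ref), 1)
  expect_equal(quantile_transform(0.5, ref), 0) # below the reference minimum
  set.seed(41)
  x <- rnorm(200)
  q <- quantile_transform(x, rnorm(500))
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[order(x)]) >= 0))
  expect_error(quantile_transform(1, numeric(0)), "non-empty")
})

test_that("raw-scale back-transform picks the smallest qualifying order statistic", {
  ref <- c(10, 20, 30, 40)
  expect_equal(raw_threshold(0.5, ref), 20)
  expect_equal(raw_threshold(0.51, ref), 30)
  expect_equal(raw_threshold(0, ref), 10)
  expect_equal(raw_threshold(1, ref), 40)
  # idempotent on reference points: transform then back-transform
  set.seed(5)
  ref <- rlnorm(50)
  for (v in sample(ref, 10)) {
    expect_equal(raw_threshold(quantile_transform(v, ref), ref), v)
  }
})
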