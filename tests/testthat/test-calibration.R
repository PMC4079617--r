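test_that("marginal exposure rate matches closed forms and Monte Carlo", {
  expect_equal(marginal_exposure_rate(0, 0), 0.5, tolerance = 1e-9)
  r <- marginal_exposure_rate(0, log(2))
  expect_gt(r, 0.5)
  expect_lt(r, 1)
  # Monte-Carlo oracle: mean of expit(a0 + log(2) Z) over 1e6 Beta(6,2) draws
  cal <- calibrate_intercept(0.5, function(a0) marginal_exposure_rate(a0, log(2)))
  set.seed(101)
  z <- rbeta(1e6, 6, 2)
  mc <- mean(plogis(cal$intercept + log(2) * z))
  se <- sd(plogis(cal$intercept + log(2) * z)) / 1e3
  expect_lt(abs(mc - 0.5), 3 * se)
})

test_that("marginal outcome rate matches closed forms and Monte Carlo", {
  # constant risk: b1 = b2 = 0 makes the marginal rate exp(b0)
  expect_equal(marginal_outcome_rate(log(0.25), 0, 0, "linear", 0, 0), 0.25,
               tolerance = 1e-9)
  expect_lt(marginal_outcome_rate(-30, log(1.5), log(2), "linear", 0, log(2)),
            1e-10)
  # generic parameters against a 1e6-draw Monte-Carlo oracle
  b0 <- -3; b1 <- log(1.5); b2 <- log(4); a0 <- -1; a1 <- log(4)
  quad <- marginal_outcome_rate(b0, b1, b2, "quadratic", a0, a1)
  set.seed(202)
  z <- rbeta(1e6, 6, 2)
  px <- plogis(a0 + a1 * z)
  g <- b2 * z + 0.5 * b2 * z^2
  term <- px * exp(b0 + b1 + g) + (1 - px) * exp(b0 + g)
  expect_lt(abs(quad - mean(term)), 3 * sd(term) / 1e3)
})

test_that("intercept calibration root-finds to tolerance and respects bounds", {
  cal <- calibrate_intercept(0.25, function(b0)
    marginal_outcome_rate(b0, 0, 0, "linear", 0, 0))
  expect_equal(cal$intercept, log(0.25), tolerance = 1e-6)
  expect_lt(abs(cal$achieved_rate - 0.25), 1e-6)
  cal2 <- calibrate_intercept(0.5, function(a0) marginal_exposure_rate(a0, log(4)))
  expect_lt(abs(marginal_exposure_rate(cal2$intercept, log(4)) - 0.5), 1e-6)
  expect_error(calibrate_intercept(1.0, identity), "strictly in")
  # a target unattainable under the probability-validity ceiling fails loudly
  expect_error(
    calibrate_intercept(0.9, function(b0)
      marginal_outcome_rate(b0, log(2), log(4), "quadratic", 0, log(4)),
      upper_bound = -(log(2) + 1.5 * log(4)), label = "impossible scenario"),
    "unattainable")
})

test_that("calibrated intercepts reproduce empirical rates on a large cohort", {
  sc <- scenario_row(1.5, 0.25, "strong", "quadratic")
  p <- calibrate_scenario(sc)
  expect_equal(p$b1, log(1.5))
  expect_equal(p$b2, p$a1)
  d <- rr_simulate(p, 1e6, seed = 33)
  se_x <- sqrt(0.5 * 0.5 / 1e6)
  se_y <- sqrt(0.25 * 0.75 / 1e6)
  expect_lt(abs(mean(d$x) - 0.5), 3 * se_x)
  expect_lt(abs(mean(d$y) - 0.25), 3 * se_y)
})

test_that("all 24 designed scenarios calibrate with valid probabilities", {
  sc <- rr_scenarios(1500)
  for (i in seq_len(nrow(sc))) {
    p <- calibrate_scenario(sc[i, ])
    g1 <- if (p$confounder == "quadratic") 1.5 * p$b2 else p$b2
    expect_lte(exp(p$b0 + p$b1 + g1), 1)
    expect_lt(abs(p$exposure_rate - 0.5), 1e-6)
    expect_lt(abs(p$outcome_rate - sc$outcome_rate[i]), 1e-6)
  }
})
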