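# 2x2 cohort with interior MLE: exposed 10/20 events, unexposed 5/20
d22 <- cohort_2x2(10, 20, 5, 20)

test_that("both estimators recover the closed-form RR on a saturated design", {
  lb <- rrfit(y ~ x, d22, method = "log_binomial")
  rp <- rrfit(y ~ x, d22, method = "robust_poisson")
  expect_equal(unname(coef(lb)[["x"]]), log(2), tolerance = 1e-10)
  expect_equal(unname(coef(rp)[["x"]]), log(2), tolerance = 1e-10)
  expect_equal(lb$rr, 2, tolerance = 1e-9)
  expect_false(lb$used_copy)
  expect_true(lb$converged && rp$converged)
})

test_that("the sandwich SE matches the two-sample closed form", {
  # sqrt((1-p1)/(n1 p1) + (1-p0)/(n0 p0)) = sqrt(0.05 + 0.15) = sqrt(0.2)
  rp <- rrfit(y ~ x, d22, method = "robust_poisson")
  expect_equal(rp$se_log_rr, sqrt(0.2), tolerance = 1e-10)
  V <- vcov(rp)
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
})

test_that("duplicating every row k times leaves estimates fixed and shrinks the sandwich SE by sqrt(k)", {
  k <- 4
  dk <- d22[rep(seq_len(nrow(d22)), each = k), ]
  rp1 <- rrfit(y ~ x, d22, method = "robust_poisson")
  rpk <- rrfit(y ~ x, dk, method = "robust_poisson")
  expect_equal(coef(rpk), coef(rp1), tolerance = 1e-9)
  expect_equal(rpk$se_log_rr, rp1$se_log_rr / sqrt(k), tolerance = 1e-9)
})

test_that("fits agree with glm and sandwich::vcovHC on a simulated cohort", {
  skip_if_not_installed("sandwich")
  p <- calibrate_scenario(scenario_row(2, 0.25, "strong", "linear"))
  d <- rr_simulate(p, 1500, seed = 21)
  rp <- rrfit(y ~ x + z, d, method = "robust_poisson")
  gp <- glm(y ~ x + z, data = d, family = poisson(link = "log"))
  expect_equal(coef(rp), coef(gp), tolerance = 1e-8)
  expect_equal(vcov(rp), unclass(sandwich::vcovHC(gp, type = "HC0")),
               tolerance = 1e-6, ignore_attr = TRUE)

  lb <- rrfit(y ~ x + z, d, method = "log_binomial")
  gb <- suppressWarnings(glm(y ~ x + z, data = d,
                             family = binomial(link = "log"),
                             start = coef(rp)))
  expect_true(gb$converged)
  expect_equal(coef(lb), coef(gb), tolerance = 1e-4)
  expect_equal(lb$se, sqrt(diag(vcov(gb))), tolerance = 1e-4)
})

test_that("the COPY estimate agrees with the direct MLE on interior fits", {
  p <- calibrate_scenario(scenario_row(1.5, 0.25, "moderate", "linear"))
  d <- rr_simulate(p, 1500, seed = 31)
  X <- cbind(1, x = d$x, z = d$z)
  direct <- rr_irls(X, d$y, "binomial_log")
  expect_true(direct$converged)
  # force the COPY route on the same data
  C <- 1e6
  cp <- rr_irls(rbind(X, X), c(d$y, 1 - d$y), "binomial_log",
                weights = c(rep(C, nrow(X)), rep(1, nrow(X))),
                control = rr_control(maxit = 2500))
  expect_true(cp$converged)
  expect_lt(max(abs(cp$coefficients - direct$coefficients)), 5e-4)
})

test_that("boundary MLEs trigger the COPY fallback and stay below p = 1", {
  # all exposed subjects have the event: direct MLE on the boundary
  db <- cohort_2x2(20, 20, 5, 20)
  direct <- rr_irls(cbind(1, x = db$x), db$y, "binomial_log")
  expect_false(direct$converged)
  lb <- rrfit(y ~ x, db, method = "log_binomial")
  expect_true(lb$converged)
  expect_true(lb$used_copy)
  expect_true(is.finite(lb$log_rr))
  expect_lt(max(lb$fitted), 1)
  # boundary RR is 1 / 0.25 = 4; COPY approximates it from inside
  expect_equal(lb$rr, 4, tolerance = 1e-3)
})

test_that("degenerate and invalid inputs are rejected or flagged, never mis-fitted", {
  d0 <- data.frame(y = rep(0, 30), x = rep(0:1, 15))
  f0 <- rrfit(y ~ x, d0, method = "log_binomial")
  expect_false(f0$converged)
  expect_true(all(is.na(coef(f0))))

  expect_error(rrfit(y ~ x, d22, copy_c = 0), "copy_c")
  dd <- transform(d22, x2 = x)
  expect_error(rrfit(y ~ x + x2, dd), "rank deficient")
  expect_error(rrfit(y ~ x - 1, d22), "intercept")
  expect_error(rr_irls(cbind(1, d22$x), d22$y, weights = rep(-1, 40)),
               "non-negative")
  d3 <- transform(d22, y = y + 1)
  expect_error(rrfit(y ~ x, d3), "binary")
})

test_that("fitted probabilities of accepted log-binomial iterates stay below 1", {
  p <- calibrate_scenario(scenario_row(1.5, 0.10, "moderate", "quadratic"))
  for (s in 1:5) {
    d <- rr_contaminate(rr_simulate(p, 1500, seed = 40 + s), 0.05)
    lb <- rrfit(y ~ x + z + I(z^2), d, method = "log_binomial")
    if (lb$converged) expect_lte(max(lb$fitted), 1 - 1e-10)
  }
})

test_that("accessor methods are consistent with the fit", {
  lb <- rrfit(y ~ x, d22, method = "log_binomial")
  expect_equal(predict(lb), lb$fitted)
  expect_equal(predict(lb, data.frame(x = c(0, 1))),
               exp(coef(lb)[1] + coef(lb)[2] * c(0, 1)), ignore_attr = TRUE)
  expect_equal(residuals(lb), d22$y - lb$fitted)
  r_p <- residuals(lb, "pearson")
  expect_equal(r_p, (d22$y - lb$fitted) / sqrt(lb$fitted * (1 - lb$fitted)))
  ci <- confint(lb, "x")
  expect_lt(ci[1], log(2)); expect_gt(ci[2], log(2))
  s <- summary(lb)
  expect_s3_class(s, "summary.rrfit")
  expect_equal(unname(s$coefficients["x", "Estimate"]), lb$log_rr)
  expect_output(print(lb), "Log-binomial")
  expect_output(print(s), "Adjusted RR")
})
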