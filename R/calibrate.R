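## expectation of f(Z) under Z ~ Beta(6, 2) by adaptive quadrature
beta_expect <- function(f, rel_tol = 1e-10) {
  stats::integrate(function(z) f(z) * stats::dbeta(z, BETA_SHAPE1, BETA_SHAPE2),
                   0, 1, rel.tol = rel_tol, abs.tol = 0,
                   subdivisions = 500L)$value
}

#' Marginal exposure rate under the logistic exposure model
#'
#' Computes `E_Z[expit(a0 + a1 Z)]` with `Z ~ Beta(6, 2)` by adaptive
#' quadrature on (0, 1). The result is monotone increasing in `a0`, which is
#' what [calibrate_intercept()] exploits.
#'
#' @param a0 Exposure-model intercept.
#' @param a1 Exposure-model slope (log 2 for moderate, log 4 for strong
#'   confounding).
#' @return The marginal probability of exposure.
#' @export
marginal_exposure_rate <- function(a0, a1) {
  beta_expect(function(z) stats::plogis(a0 + a1 * z))
}

#' Marginal outcome rate under the log-binomial outcome model
#'
#' Computes `E_Z[p_x(Z) exp(l(1, Z)) + (1 - p_x(Z)) exp(l(0, Z))]` where
#' `p_x(z) = expit(a0 + a1 z)` is the exposure probability and `l(x, z)` the
#' log outcome probability ([risk_linpred()]), with `Z ~ Beta(6, 2)`, by
#' adaptive quadrature. Monotone increasing in `b0`.
#'
#' @param b0 Outcome-model intercept (log scale).
#' @param b1 Log relative risk.
#' @param b2 Confounder coefficient on the log-risk scale.
#' @param confounder `"linear"` or `"quadratic"`.
#' @param a0,a1 Exposure-model intercept and slope.
#' @return The marginal probability of the outcome.
#' @export
marginal_outcome_rate <- function(b0, b1, b2, confounder, a0, a1) {
  pp <- list(b0 = b0, b1 = b1, b2 = b2, confounder = confounder)
  beta_expect(function(z) {
    px <- stats::plogis(a0 + a1 * z)
    px * exp(risk_linpred(pp, 1, z)) + (1 - px) * exp(risk_linpred(pp, 0, z))
  })
}

#' Root-find an intercept matching a target marginal rate
#'
#' Searches an intercept so that a monotone marginal-rate function hits the
#' target, as the study design requires for both the exposure intercept `a0`
#' (target 50% exposure) and the outcome intercept `b0` (target outcome
#' rate). Brent's method brackets the root; the achieved rate must match the
#' target to within `rate_tol`. When `upper_bound` is supplied (the `b0`
#' ceiling `-(b1 + g(1))` guaranteeing all outcome probabilities <= 1), the
#' search is confined below it and an unattainable target raises an explicit
#' calibration error rather than silently truncating probabilities.
#'
#' @param target Target marginal rate, strictly inside (0, 1).
#' @param rate_fn Monotone-increasing function mapping an intercept to a
#'   marginal rate.
#' @param lower,upper Initial search bracket for the intercept.
#' @param upper_bound Optional validity ceiling on the intercept.
#' @param tol Root-finder tolerance on the intercept.
#' @param rate_tol Required agreement between achieved and target rate.
#' @param label Scenario label used in error messages.
#' @return A list of class `"rr_calibration"` with `intercept`,
#'   `achieved_rate`, `target`, `tolerance` and `method = "quadrature"`.
#' @export
calibrate_intercept <- function(target, rate_fn, lower = -50, upper = 50,
                                upper_bound = NULL, tol = 1e-10,
                                rate_tol = 1e-6, label = "intercept") {
  if (!is.finite(target) || target <= 0 || target >= 1)
    stop(sprintf("calibration target for %s must lie strictly in (0, 1)", label))
  if (!is.null(upper_bound)) {
    upper <- min(upper, upper_bound)
    if (rate_fn(upper_bound) < target - rate_tol)
      stop(sprintf(paste0("calibration failure for %s: target rate %.4g is ",
                          "unattainable with all probabilities <= 1 ",
                          "(rate at the validity bound is %.4g)"),
                   label, target, rate_fn(upper_bound)))
  }
  f <- function(b) rate_fn(b) - target
  if (f(lower) > 0 || f(upper) < 0)
    stop(sprintf("calibration bracket for %s does not contain the root", label))
  root <- stats::uniroot(f, c(lower, upper), tol = tol)$root
  achieved <- rate_fn(root)
  if (abs(achieved - target) > rate_tol)
    stop(sprintf("calibration for %s achieved %.8f, outside tolerance of target %.8f",
                 label, achieved, target))
  structure(list(intercept = root, achieved_rate = achieved, target = target,
                 tolerance = rate_tol, method = "quadrature"),
            class = "rr_calibration")
}

#' Resolve the generating coefficients of a scenario
#'
#' Turns one scenario row ([rr_scenarios()]) into fully calibrated
#' generating-model parameters. The exposure intercept `a0` is calibrated
#' first so that the marginal exposure rate is exactly 50%; it is then frozen
#' while the outcome intercept `b0` is calibrated to the scenario's marginal
#' outcome rate, subject to the validity ceiling `b0 <= -(b1 + g(1))` that
#' keeps every subject-level outcome probability at or below 1.
#'
#' @param scenario A one-row data frame (or list) with `true_rr`,
#'   `outcome_rate`, `exposure_rate`, `association`, `confounder` and
#'   optionally `scenario_id`; slopes `a1`, `b1`, `b2` are taken if present,
#'   else derived (`a1 = b2 =` log 2 or log 4 by association,
#'   `b1 = log(true_rr)`).
#' @return A list of class `"rr_params"` with `a0`, `a1`, `b0`, `b1`, `b2`,
#'   `confounder`, the achieved marginal rates, and the scenario id.
#' @export
calibrate_scenario <- function(scenario) {
  sc <- as.list(scenario)
  a1 <- if (!is.null(sc$a1)) sc$a1 else assoc_slope(sc$association)
  b1 <- if (!is.null(sc$b1)) sc$b1 else log(sc$true_rr)
  b2 <- if (!is.null(sc$b2)) sc$b2 else a1
  id <- if (!is.null(sc$scenario_id)) sc$scenario_id else "scenario"
  exposure_rate <- if (!is.null(sc$exposure_rate)) sc$exposure_rate else EXPOSURE_RATE

  cal_a <- calibrate_intercept(exposure_rate,
                               function(a0) marginal_exposure_rate(a0, a1),
                               label = paste0(id, " (exposure intercept a0)"))
  g1 <- confounder_effect(b2, 1, sc$confounder)
  b0_ceiling <- -(b1 + g1)
  cal_b <- calibrate_intercept(
    sc$outcome_rate,
    function(b0) marginal_outcome_rate(b0, b1, b2, sc$confounder,
                                       cal_a$intercept, a1),
    upper_bound = b0_ceiling,
    label = paste0(id, " (outcome intercept b0)"))

  structure(list(a0 = cal_a$intercept, a1 = a1,
                 b0 = cal_b$intercept, b1 = b1, b2 = b2,
                 confounder = sc$confounder,
                 scenario_id = id,
                 exposure_rate = cal_a$achieved_rate,
                 outcome_rate = cal_b$achieved_rate),
            class = "rr_params")
}

#' @export
print.rr_params <- function(x, ...) {
  cat("Calibrated generating parameters for", x$scenario_id, "\n")
  cat(sprintf("  exposure model: logit(p_x) = %.6f + %.6f z  (marginal rate %.6f)\n",
              x$a0, x$a1, x$exposure_rate))
  form <- if (x$confounder == "quadratic")
    sprintf("%.6f + %.6f x + %.6f z + %.6f z^2", x$b0, x$b1, x$b2, 0.5 * x$b2)
  else sprintf("%.6f + %.6f x + %.6f z", x$b0, x$b1, x$b2)
  cat(sprintf("  outcome model:  log(p_y) = %s  (marginal rate %.6f)\n",
              form, x$outcome_rate))
  invisible(x)
}
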