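#' Control parameters for relative-risk model fitting
#'
#' Convergence and step-size settings for the iteratively reweighted least
#' squares (IRLS) fitter used by [rrfit()].
#'
#' @param epsilon Relative change in deviance below which the fit is declared
#'   converged (jointly with `coef_tol`).
#' @param coef_tol Maximum absolute coefficient change below which the fit is
#'   declared converged (jointly with `epsilon`).
#' @param maxit Iteration cap; reaching it yields a non-converged result, not
#'   an error.
#' @param copy_maxit Iteration cap for the COPY refit. The COPY likelihood is
#'   concave with an interior optimum, but its curvature near the validity
#'   boundary makes first-order scoring steps small, so a larger cap than for
#'   direct fits is appropriate.
#' @param max_halvings Maximum number of step halvings per iteration when a
#'   proposed step leaves the valid region (fitted probability >= 1 for the
#'   log-binomial model) or increases the deviance.
#' @param p_max Upper bound enforced on fitted probabilities of the
#'   log-binomial model at every accepted iterate.
#' @param p_boundary A log-binomial fit that meets the convergence criteria
#'   but has a fitted probability above this value is treated as a boundary
#'   solution (the step cap against `p_max` can masquerade as convergence)
#'   and reported as non-converged, which triggers the COPY fallback in
#'   [rrfit()].
#'
#' @return A list of class `"rr_control"`.
#' @export
rr_control <- function(epsilon = 1e-8, coef_tol = 1e-6, maxit = 100L,
                       copy_maxit = 2500L, max_halvings = 30L,
                       p_max = 1 - 1e-10, p_boundary = 1 - 1e-8) {
  stopifnot(epsilon > 0, coef_tol > 0, maxit >= 1, copy_maxit >= 1,
            max_halvings >= 1,
            p_max > 0, p_max < 1, p_boundary < p_max)
  structure(list(epsilon = epsilon, coef_tol = coef_tol,
                 maxit = as.integer(maxit),
                 copy_maxit = as.integer(copy_maxit),
                 max_halvings = as.integer(max_halvings),
                 p_max = p_max, eta_max = log(p_max),
                 eta_boundary = log(p_boundary)),
            class = "rr_control")
}

## deviance of a log-link fit to binary y (binomial) or of the Poisson
## working model; y need not be 0/1 for the Poisson branch
log_link_deviance <- function(y, mu, w, family) {
  if (family == "binomial_log") {
    ll <- w * (y * log(mu) + (1 - y) * log1p(-mu))
    -2 * sum(ll)
  } else {
    2 * sum(w * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
  }
}

#' Low-level IRLS for log-link GLMs
#'
#' Fits a generalized linear model with logarithmic link by iteratively
#' reweighted least squares, either with a binomial variance (the
#' log-binomial model, whose exponentiated coefficients are adjusted relative
#' risks) or a Poisson variance (the working model of robust Poisson
#' regression). For the binomial family every accepted iterate is constrained
#' to fitted probabilities strictly below 1 via step halving, and steps are
#' additionally required not to increase the deviance.
#'
#' This is the computational kernel behind [rrfit()]; most users should call
#' that instead.
#'
#' @param X Design matrix (full column rank required).
#' @param y Response vector; 0/1 for `binomial_log`.
#' @param family `"binomial_log"` or `"poisson_log"`.
#' @param weights Optional non-negative prior weights (default all 1).
#' @param start Optional starting coefficient vector. For `binomial_log` the
#'   default start is the Poisson solution when it is valid (all fitted
#'   probabilities < 1), else intercept-only at `log(mean(y))`.
#' @param control An [rr_control()] list.
#'
#' @return A list with elements `coefficients`, `eta`, `fitted` (mean scale),
#'   `deviance`, `converged`, `boundary` (`TRUE` when the fit stalled against
#'   the probability constraint), `iterations`, and `info` (the expected
#'   information matrix `X'WX` at the final coefficients).
#' @export
rr_irls <- function(X, y, family = c("binomial_log", "poisson_log"),
                    weights = NULL, start = NULL, control = rr_control()) {
  family <- match.arg(family)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length of 'y' does not match nrow(X)")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not all zero")
  if (family == "binomial_log" && !all(y %in% c(0, 1)))
    stop("binomial_log requires a 0/1 response")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")

  wm <- sum(weights * y) / sum(weights)
  failed <- function(boundary = FALSE, it = 0L) {
    list(coefficients = stats::setNames(rep(NA_real_, p), colnames(X)),
         eta = rep(NA_real_, n),
         fitted = rep(NA_real_, n), deviance = NA_real_, converged = FALSE,
         boundary = boundary, iterations = it, info = NULL)
  }
  if (wm <= 0 || (family == "binomial_log" && wm >= 1)) return(failed())

  has_int <- all(X[, 1] == 1)
  fallback_start <- function() {
    b <- numeric(p)
    if (has_int) b[1] <- log(wm) else b[] <- 0
    b
  }
  if (is.null(start)) {
    if (family == "binomial_log") {
      ps <- rr_irls(X, y, "poisson_log", weights = weights, control = control)
      start <- ps$coefficients
      if (!ps$converged || anyNA(start) ||
          any(drop(X %*% start) >= control$eta_max))
        start <- fallback_start()
    } else {
      start <- fallback_start()
    }
  }
  beta <- start
  eta <- drop(X %*% beta)
  if (family == "binomial_log" && any(eta >= control$eta_max)) {
    beta <- fallback_start()
    eta <- drop(X %*% beta)
    if (any(eta >= control$eta_max)) return(failed(boundary = TRUE))
  }
  mu <- exp(eta)
  dev <- log_link_deviance(y, mu, weights, family)

  converged <- FALSE
  boundary <- FALSE
  it <- 0L
  while (it < control$maxit) {
    it <- it + 1L
    W <- if (family == "binomial_log") weights * mu / (1 - mu) else weights * mu
    z <- eta + (y - mu) / mu
    XtWX <- crossprod(X, X * W)
    XtWz <- crossprod(X, W * z)
    beta_new <- tryCatch(drop(solve(XtWX, XtWz)), error = function(e) NULL)
    if (is.null(beta_new) || anyNA(beta_new)) return(failed(it = it))
    delta <- beta_new - beta

    ## longest feasible step along the scoring direction: the constraint
    ## eta < eta_max (binomial; 700 for Poisson overflow) is linear in beta,
    ## so the largest valid multiple of delta has a closed form
    eta_dir <- drop(X %*% delta)
    cap <- if (family == "binomial_log") control$eta_max else 700
    rising <- eta_dir > 0
    hit_bound <- any(rising & (eta + eta_dir >= cap))
    step_max <- if (any(rising)) min((cap - eta[rising]) / eta_dir[rising])
                else Inf
    step <- min(1, 0.95 * step_max)
    accepted <- FALSE
    for (h in seq_len(control$max_halvings + 1L)) {
      b_try <- beta + step * delta
      eta_try <- drop(X %*% b_try)
      if (all(eta_try < cap)) {
        mu_try <- exp(eta_try)
        dev_try <- log_link_deviance(y, mu_try, weights, family)
        if (is.finite(dev_try) && dev_try <= dev * (1 + 1e-12) + 1e-12) {
          accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!accepted) {
      boundary <- hit_bound
      break
    }
    applied <- step * delta
    beta <- b_try
    eta <- eta_try
    mu <- mu_try
    dev_old <- dev
    dev <- dev_try
    ## second clause: the deviance change is below the floating-point
    ## resolution of an n-term weighted sum, so no further progress is
    ## measurable (relevant for heavily weighted COPY fits)
    dev_floor <- n * .Machine$double.eps * (abs(dev) + 1)
    if ((abs(dev_old - dev) / (abs(dev_old) + 0.1) < control$epsilon &&
         max(abs(applied)) < control$coef_tol) ||
        abs(dev_old - dev) <= dev_floor) {
      converged <- TRUE
      break
    }
  }

  if (converged && family == "binomial_log" &&
      max(eta) > control$eta_boundary) {
    ## the iterates satisfied the stopping rule only because the validity
    ## cap throttled the steps: this is a boundary MLE, not convergence
    converged <- FALSE
    boundary <- TRUE
  }
  W <- if (family == "binomial_log") weights * mu / (1 - mu) else weights * mu
  list(coefficients = stats::setNames(beta, colnames(X)), eta = eta,
       fitted = mu, deviance = dev, converged = converged,
       boundary = boundary, iterations = it, info = crossprod(X, X * W))
}

## binomial information on the original (unit-weight) data at given
## coefficients; used for SEs of COPY fits
binomial_log_info <- function(X, beta, weights) {
  mu <- exp(drop(X %*% beta))
  crossprod(X, X * (weights * mu / (1 - mu)))
}

## log-binomial fit with COPY fallback, on a raw design matrix
fit_log_binomial_X <- function(X, y, weights = NULL, copy_c = 1e6,
                               control = rr_control()) {
  if (!is.numeric(copy_c) || length(copy_c) != 1 || copy_c < 1)
    stop("'copy_c' must be a single number >= 1")
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (all(y == y[1])) {
    ## a constant outcome has no interior MLE and the COPY trick would
    ## manufacture one; flag instead of estimating
    return(list(coefficients = stats::setNames(rep(NA_real_, ncol(X)),
                                               colnames(X)),
                vcov = NULL, fitted = rep(NA_real_, nrow(X)),
                converged = FALSE, used_copy = FALSE, iterations = 0L))
  }
  direct <- rr_irls(X, y, "binomial_log", weights = weights, control = control)
  if (direct$converged) {
    vc <- tryCatch(solve(direct$info), error = function(e) NULL)
    return(list(coefficients = direct$coefficients,
                vcov = vc, fitted = direct$fitted,
                converged = TRUE, used_copy = FALSE,
                iterations = direct$iterations))
  }
  ## COPY method: weight C on the original data, weight 1 on an
  ## outcome-reversed copy, pulling the MLE into the interior
  X2 <- rbind(X, X)
  y2 <- c(y, 1 - y)
  w2 <- c(weights * copy_c, weights)
  copy_control <- control
  copy_control$maxit <- control$copy_maxit
  cp <- rr_irls(X2, y2, "binomial_log", weights = w2, control = copy_control)
  if (!cp$converged || anyNA(cp$coefficients)) {
    return(list(coefficients = stats::setNames(rep(NA_real_, ncol(X)),
                                               colnames(X)),
                vcov = NULL,
                fitted = rep(NA_real_, nrow(X)), converged = FALSE,
                used_copy = TRUE, iterations = direct$iterations + cp$iterations))
  }
  info <- binomial_log_info(X, cp$coefficients, weights)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  list(coefficients = cp$coefficients, vcov = vc,
       fitted = exp(drop(X %*% cp$coefficients)),
       converged = TRUE, used_copy = TRUE,
       iterations = direct$iterations + cp$iterations)
}

## robust Poisson fit on a raw design matrix: Poisson-ML point estimates
## (= independence GEE) with sandwich covariance A^{-1} B A^{-1}
fit_robust_poisson_X <- function(X, y, weights = NULL, control = rr_control()) {
  if (is.null(weights)) weights <- rep(1, nrow(X))
  ps <- rr_irls(X, y, "poisson_log", weights = weights, control = control)
  if (!ps$converged || anyNA(ps$coefficients)) {
    return(list(coefficients = stats::setNames(rep(NA_real_, ncol(X)),
                                               colnames(X)),
                vcov = NULL,
                fitted = rep(NA_real_, nrow(X)), converged = FALSE,
                used_copy = FALSE, iterations = ps$iterations))
  }
  res <- weights * (y - ps$fitted)
  A_inv <- tryCatch(solve(ps$info), error = function(e) NULL)
  vc <- if (is.null(A_inv)) NULL else {
    B <- crossprod(X * res)
    V <- A_inv %*% B %*% A_inv
    (V + t(V)) / 2
  }
  list(coefficients = ps$coefficients, vcov = vc, fitted = ps$fitted,
       converged = TRUE, used_copy = FALSE, iterations = ps$iterations)
}

#' Fit a relative-risk regression model for a binary outcome
#'
#' Estimates adjusted relative risks (risk ratios) for a common binary
#' outcome by one of the two standard model-based approaches:
#'
#' * `method = "log_binomial"`: maximum likelihood for a binomial GLM with
#'   log link, fitted by IRLS with fitted probabilities constrained below 1.
#'   When the direct fit does not converge (the MLE lies on or near the
#'   boundary of the parameter space), the COPY method is used as a fallback:
#'   the model is refitted to the original data with weight `copy_c` stacked
#'   with an outcome-reversed copy with weight 1, which moves the approximate
#'   MLE into the interior. Standard errors are information based, evaluated
#'   on the original data.
#' * `method = "robust_poisson"`: the modified Poisson approach -- a Poisson
#'   working GLM with log link (whose point estimates coincide with an
#'   independence-GEE fit), with the classical sandwich variance estimator
#'   correcting the misspecified Poisson variance.
#'
#' The exponentiated coefficient of the exposure term is the adjusted
#' relative risk.
#'
#' @param formula Model formula, e.g. `y ~ x + z`. An intercept is required.
#' @param data Data frame (one row per subject) containing the outcome,
#'   exposure and covariates; any delimited table read with
#'   [utils::read.csv()] works.
#' @param method `"log_binomial"` or `"robust_poisson"`.
#' @param exposure Name of the model term whose coefficient is the log
#'   relative risk of interest. Defaults to the first non-intercept term.
#' @param copy_c Number of virtual copies `C` for the COPY fallback
#'   (log-binomial only); default 1e6.
#' @param weights Optional non-negative prior weights.
#' @param control An [rr_control()] list.
#'
#' @return An object of class `"rrfit"` with components `coefficients`,
#'   `vcov`, `log_rr`, `se_log_rr`, `rr`, `converged`, `used_copy`,
#'   `iterations`, `method`, `exposure`, `fitted`, `n` and `call`. Methods:
#'   [print.rrfit()], [summary.rrfit()], `coef`, `vcov`, [confint.rrfit()],
#'   [predict.rrfit()], [residuals.rrfit()].
#'
#' @examples
#' d <- data.frame(y = rep(c(1, 0, 1, 0), c(10, 10, 5, 15)),
#'                 x = rep(c(1, 0), each = 20))
#' fit <- rrfit(y ~ x, d, method = "robust_poisson")
#' exp(coef(fit)["x"])  # risk ratio 0.5 / 0.25 = 2
#' @export
rrfit <- function(formula, data, method = c("log_binomial", "robust_poisson"),
                  exposure = NULL, copy_c = 1e6, weights = NULL,
                  control = rr_control()) {
  method <- match.arg(method)
  cl <- match.call()
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  mt <- attr(mf, "terms")
  if (attr(mt, "intercept") != 1)
    stop("relative-risk models require an intercept")
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1)))
    stop("the outcome must be binary (0/1, logical, or a two-level factor)")
  X <- stats::model.matrix(mt, mf)
  if (ncol(X) < 2) stop("the model must contain at least one exposure term")
  if (is.null(exposure)) exposure <- colnames(X)[2]
  if (!exposure %in% colnames(X))
    stop(sprintf("exposure term '%s' is not a column of the design", exposure))

  fit <- switch(method,
    log_binomial = fit_log_binomial_X(X, y, weights = weights,
                                      copy_c = copy_c, control = control),
    robust_poisson = fit_robust_poisson_X(X, y, weights = weights,
                                          control = control))
  se <- if (is.null(fit$vcov)) rep(NA_real_, ncol(X))
        else sqrt(pmax(diag(fit$vcov), 0))
  names(se) <- colnames(X)
  log_rr <- unname(fit$coefficients[exposure])
  structure(list(coefficients = fit$coefficients,
                 vcov = fit$vcov, se = se,
                 log_rr = log_rr, se_log_rr = unname(se[exposure]),
                 rr = exp(log_rr),
                 converged = fit$converged, used_copy = fit$used_copy,
                 iterations = fit$iterations, method = method,
                 exposure = exposure, fitted = fit$fitted, y = y,
                 n = nrow(X), terms = mt, call = cl),
            class = "rrfit")
}

#' @export
print.rrfit <- function(x, digits = 4, ...) {
  lab <- c(log_binomial = "Log-binomial regression",
           robust_poisson = "Robust (modified) Poisson regression")[x$method]
  cat(lab, "\n")
  if (x$method == "log_binomial" && isTRUE(x$used_copy))
    cat("(COPY-method fit: direct MLE on the boundary)\n")
  cat("Call: ", deparse(x$call), "\n\n")
  if (!x$converged) {
    cat("Model did not converge; no estimates reported.\n")
    return(invisible(x))
  }
  cat("Coefficients (log relative-risk scale):\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nAdjusted RR (%s): %.*f   log RR: %.*f (SE %.*f)\n",
              x$exposure, digits, x$rr, digits, x$log_rr, digits, x$se_log_rr))
  invisible(x)
}

#' @export
coef.rrfit <- function(object, ...) object$coefficients

#' @export
vcov.rrfit <- function(object, ...) object$vcov

#' Confidence intervals for relative-risk model coefficients
#'
#' Wald intervals on the log relative-risk scale (sandwich-based for robust
#' Poisson fits, information-based for log-binomial fits).
#'
#' @param object An [rrfit()] object.
#' @param parm Coefficients to include (names or indices); default all.
#' @param level Confidence level.
#' @param ... Unused.
#' @return A matrix of lower and upper limits.
#' @export
confint.rrfit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  a <- (1 - level) / 2
  q <- stats::qnorm(1 - a)
  ci <- cbind(cf[parm] - q * object$se[parm], cf[parm] + q * object$se[parm])
  colnames(ci) <- sprintf("%.1f %%", 100 * c(a, 1 - a))
  ci
}

#' Summarise a relative-risk model fit
#'
#' @param object An [rrfit()] object.
#' @param level Confidence level for the Wald interval on the RR.
#' @param ... Unused.
#' @return An object of class `"summary.rrfit"`: the coefficient table (log
#'   scale) with z statistics and p values, plus the RR of interest and its
#'   Wald interval.
#' @export
summary.rrfit <- function(object, level = 0.95, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  ci <- exp(confint.rrfit(object, parm = object$exposure, level = level))
  structure(list(coefficients = tab, rr = object$rr, rr_ci = drop(ci),
                 level = level, method = object$method,
                 exposure = object$exposure, converged = object$converged,
                 used_copy = object$used_copy, n = object$n,
                 call = object$call),
            class = "summary.rrfit")
}

#' @export
print.summary.rrfit <- function(x, digits = 4, ...) {
  lab <- c(log_binomial = "Log-binomial regression",
           robust_poisson = "Robust (modified) Poisson regression")[x$method]
  cat(lab, " (n = ", x$n, ")\n", sep = "")
  if (!x$converged) {
    cat("Model did not converge.\n")
    return(invisible(x))
  }
  if (isTRUE(x$used_copy)) cat("Fitted by the COPY method.\n")
  cat("\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nAdjusted RR (%s): %.*f, %g%% CI [%.*f, %.*f]\n",
              x$exposure, digits, x$rr, 100 * x$level,
              digits, x$rr_ci[1], digits, x$rr_ci[2]))
  invisible(x)
}

#' Predict from a relative-risk model fit
#'
#' @param object An [rrfit()] object.
#' @param newdata Optional data frame of covariates; defaults to the fitted
#'   values on the training data.
#' @param type `"response"` (outcome probability) or `"link"` (log scale).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rrfit <- function(object, newdata = NULL,
                          type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    mu <- object$fitted
    return(if (type == "response") mu else log(mu))
  }
  tt <- stats::delete.response(object$terms)
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  eta <- drop(X %*% object$coefficients)
  if (type == "response") exp(eta) else eta
}

#' Residuals of a relative-risk model fit
#'
#' @param object An [rrfit()] object.
#' @param type `"response"` (`y - p`) or `"pearson"`
#'   (`(y - p) / sqrt(v(p))`, with the variance function of the fitted
#'   working family).
#' @param ... Unused.
#' @return Numeric vector of residuals.
#' @export
residuals.rrfit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson") {
    v <- if (object$method == "log_binomial")
      object$fitted * (1 - object$fitted) else object$fitted
    r <- r / sqrt(v)
  }
  r
}
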