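#' Relative bias of log relative-risk estimates
#'
#' `100 * (mean(log_rr_hats) - log(true_rr)) / log(true_rr)`: the average
#' estimated log RR across simulation replicates, minus the true log RR,
#' as a percentage of the true log RR.
#'
#' @param log_rr_hats Vector of estimated log relative risks (one per
#'   replicate).
#' @param true_rr The true relative risk (must differ from 1, where relative
#'   bias is undefined).
#' @return Relative bias in percent.
#' @export
relative_bias <- function(log_rr_hats, true_rr) {
  if (length(log_rr_hats) == 0) stop("no estimates supplied")
  if (!is.finite(true_rr) || true_rr <= 0 || true_rr == 1)
    stop("relative bias is undefined for true_rr = 1")
  100 * (mean(log_rr_hats) - log(true_rr)) / log(true_rr)
}

#' Empirical standard error of log relative-risk estimates
#'
#' Sample standard deviation (denominator `n - 1`) of the log-scale
#' estimates across replicates.
#'
#' @inheritParams relative_bias
#' @return The empirical SE on the log-RR scale.
#' @export
empirical_se <- function(log_rr_hats) {
  if (length(log_rr_hats) < 2) stop("at least 2 estimates are required")
  stats::sd(log_rr_hats)
}

#' Mean square error of log relative-risk estimates
#'
#' Squared bias on the log scale plus the empirical variance (`n - 1`
#' denominator, the square of [empirical_se()]).
#'
#' @inheritParams relative_bias
#' @return The MSE on the log-RR scale.
#' @export
mse_log <- function(log_rr_hats, true_rr) {
  if (length(log_rr_hats) < 2) stop("at least 2 estimates are required")
  if (!is.finite(true_rr) || true_rr <= 0)
    stop("'true_rr' must be a positive number")
  (mean(log_rr_hats) - log(true_rr))^2 + stats::var(log_rr_hats)
}

## summarise one (level, method) cell from replicate-wise estimates
summarize_cell <- function(log_rr_hats, converged, true_rr) {
  use <- converged & is.finite(log_rr_hats)
  est <- log_rr_hats[use]
  data.frame(n_replicates = length(log_rr_hats),
             n_used = length(est),
             convergence_rate = mean(converged),
             rel_bias_pct = if (length(est) >= 1) relative_bias(est, true_rr) else NA_real_,
             emp_se = if (length(est) >= 2) empirical_se(est) else NA_real_,
             mse = if (length(est) >= 2) mse_log(est, true_rr) else NA_real_)
}
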