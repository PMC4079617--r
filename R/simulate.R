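#' Generate one replicate cohort from a calibrated scenario
#'
#' Draws a cohort of `n` subjects: confounder `Z ~ Beta(6, 2)` (mean 0.75; if
#' `100 Z` is age, an elderly population), exposure
#' `X | Z ~ Bernoulli(expit(a0 + a1 Z))`, and outcome
#' `Y | X, Z ~ Bernoulli(exp(l(X, Z)))` with `l` the log-risk linear
#' predictor ([risk_linpred()]). The true per-subject outcome probability is
#' stored so that contamination can target its extremes.
#'
#' @param params Calibrated generating parameters ([calibrate_scenario()]).
#' @param n Number of subjects (>= 2).
#' @param seed Optional integer seed; the draw is fully reproducible from it.
#' @return A data frame with columns `id`, `z`, `x`, `y`, `p_y` and `flipped`
#'   (all `FALSE` for a pristine cohort), with the seed kept in
#'   `attr(, "seed")`.
#' @export
rr_simulate <- function(params, n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n))
    stop("'n' must be a single integer >= 2")
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rbeta(n, BETA_SHAPE1, BETA_SHAPE2)
  x <- stats::rbinom(n, 1, stats::plogis(params$a0 + params$a1 * z))
  p_y <- exp(risk_linpred(params, x, z))
  if (any(p_y > 1))
    stop(sprintf("generated outcome probability exceeds 1 in %s (max %.6f); calibration should preclude this",
                 params$scenario_id, max(p_y)))
  y <- stats::rbinom(n, 1, p_y)
  d <- data.frame(id = seq_len(n), z = z, x = x, y = y, p_y = p_y,
                  flipped = FALSE)
  attr(d, "seed") <- seed
  d
}

## per-tail flip count for a contamination level
tail_flip_count <- function(level, n) floor(level / 2 * n)

#' Contaminate a cohort by flipping extreme-probability outcomes
#'
#' Emulates gross outcome misclassification (e.g. data-entry errors) that
#' lands on leverage points: the outcomes of the records whose *true*
#' outcome probability `p_y` is most extreme are flipped (`Y` becomes
#' `1 - Y`). At the 2% level the bottom 1% and top 1% of records by `p_y`
#' are flipped (`floor(0.01 n)` per tail); at the 5% level, 2.5% per tail.
#' Ranking uses the true probability with ties broken by record index, so
#' flip counts are exact. `z`, `x` and `p_y` are untouched; applying the same
#' contamination twice restores the original outcomes.
#'
#' @param data A cohort from [rr_simulate()] (needs columns `y`, `p_y`,
#'   `flipped`).
#' @param level One of 0, 0.02 or 0.05 (the designed contamination rates).
#' @return The contaminated cohort, with `flipped` marking toggled records.
#' @export
rr_contaminate <- function(data, level) {
  if (!is.numeric(level) || length(level) != 1 ||
      !isTRUE(any(abs(level - c(0, 0.02, 0.05)) < 1e-12)))
    stop("'level' must be one of 0, 0.02, 0.05")
  if (level == 0) return(data)
  n <- nrow(data)
  k <- tail_flip_count(level, n)
  if (k == 0) return(data)
  ord <- order(data$p_y)  # stable: ties broken by record index
  idx <- c(ord[seq_len(k)], ord[n - k + seq_len(k)])
  one <- if (is.integer(data$y)) 1L else 1
  data$y[idx] <- one - data$y[idx]
  data$flipped[idx] <- !data$flipped[idx]
  data
}
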