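## allowed design values for the simulation grid
RR_LEVELS <- c(1.5, 2.0)
OUTCOME_RATES <- c(0.10, 0.25, 0.40)
ASSOC_LEVELS <- c("moderate", "strong")
CONFOUNDER_FORMS <- c("linear", "quadratic")
EXPOSURE_RATE <- 0.5
BETA_SHAPE1 <- 6
BETA_SHAPE2 <- 2

assoc_slope <- function(association) {
  ifelse(association == "moderate", log(2), log(4))
}

#' Enumerate the simulation scenario grid
#'
#' Builds the full factorial design of the contamination study: true relative
#' risk (1.5 or 2), marginal outcome rate (10/25/40%), strength of the
#' confounder's association with exposure and outcome (moderate = log 2,
#' strong = log 4, used for both the exposure-model slope `a1` and the
#' outcome-model confounder coefficient `b2`), and the functional form of the
#' confounder in the outcome model (linear or quadratic). Crossing the four
#' factors yields 24 scenarios per sample size; the marginal exposure rate is
#' fixed at 50% throughout.
#'
#' @param sample_sizes Integer vector of cohort sizes (each >= 2); one block
#'   of 24 scenarios is produced per size.
#' @param true_rr,outcome_rate,association,confounder Optional subsets of the
#'   designed levels, to restrict the grid.
#'
#' @return A data frame with one row per scenario, columns `scenario_id`,
#'   `true_rr`, `outcome_rate`, `exposure_rate`, `association`, `confounder`,
#'   `n`, and the resolved slopes `a1`, `b1` (= log true RR) and `b2` (= `a1`).
#'   Rows are ordered by RR, outcome rate, association, confounder form, then
#'   sample size.
#' @examples
#' nrow(rr_scenarios(1500))        # 24
#' nrow(rr_scenarios(c(1500, 500)))  # 48
#' @export
rr_scenarios <- function(sample_sizes = 1500,
                         true_rr = RR_LEVELS,
                         outcome_rate = OUTCOME_RATES,
                         association = ASSOC_LEVELS,
                         confounder = CONFOUNDER_FORMS) {
  if (length(sample_sizes) == 0)
    stop("'sample_sizes' must be non-empty")
  if (any(!is.finite(sample_sizes)) || any(sample_sizes < 2) ||
      any(sample_sizes != round(sample_sizes)))
    stop("each sample size must be an integer >= 2")
  if (!all(true_rr %in% RR_LEVELS))
    stop("'true_rr' values must be among 1.5 and 2")
  if (!all(outcome_rate %in% OUTCOME_RATES))
    stop("'outcome_rate' values must be among 0.10, 0.25, 0.40")
  association <- match.arg(association, ASSOC_LEVELS, several.ok = TRUE)
  confounder <- match.arg(confounder, CONFOUNDER_FORMS, several.ok = TRUE)

  g <- expand.grid(n = as.integer(sample_sizes),
                   confounder = confounder,
                   association = association,
                   outcome_rate = outcome_rate,
                   true_rr = true_rr,
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$true_rr, g$outcome_rate, g$association, g$confounder, g$n), ,
         drop = FALSE]
  g$exposure_rate <- EXPOSURE_RATE
  g$a1 <- assoc_slope(g$association)
  g$b1 <- log(g$true_rr)
  g$b2 <- g$a1
  g$scenario_id <- sprintf("RR%g_P%g_%s_%s_n%d", g$true_rr,
                           100 * g$outcome_rate, g$association, g$confounder,
                           g$n)
  rownames(g) <- NULL
  g[, c("scenario_id", "true_rr", "outcome_rate", "exposure_rate",
        "association", "confounder", "n", "a1", "b1", "b2")]
}

## confounder effect g(z) on the log-risk scale
confounder_effect <- function(b2, z, confounder) {
  if (confounder == "quadratic") b2 * z + 0.5 * b2 * z^2 else b2 * z
}

#' Linear predictor of the outcome model on the log-probability scale
#'
#' Evaluates `b0 + b1*x + b2*z` (linear confounder) or
#' `b0 + b1*x + b2*z + 0.5*b2*z^2` (quadratic confounder). By construction
#' the ratio of outcome probabilities at `x = 1` versus `x = 0` equals
#' `exp(b1)` for every `z`, i.e. the adjusted relative risk is constant in
#' the confounder.
#'
#' @param params A list or one-row data frame with `b0`, `b1`, `b2` and
#'   `confounder` (`"linear"` or `"quadratic"`), e.g. from
#'   [calibrate_scenario()].
#' @param x Exposure indicator(s), 0 or 1.
#' @param z Confounder value(s) in (0, 1).
#' @return Log outcome probability, vectorised over `x` and `z`.
#' @export
risk_linpred <- function(params, x, z) {
  if (!all(x %in% c(0, 1))) stop("'x' must be 0/1")
  if (any(z <= 0) || any(z >= 1)) stop("'z' must lie in the open interval (0, 1)")
  params$b0 + params$b1 * x + confounder_effect(params$b2, z, params$confounder)
}
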