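## design matrix of the fitted mean model: {1, x, z} for linear scenarios,
## {1, x, z, z^2} with a free quadratic coefficient for quadratic scenarios
scenario_design_matrix <- function(data, confounder) {
  if (confounder == "quadratic")
    cbind(`(Intercept)` = 1, x = data$x, z = data$z, `I(z^2)` = data$z^2)
  else
    cbind(`(Intercept)` = 1, x = data$x, z = data$z)
}

#' Run the Monte-Carlo study for one scenario
#'
#' For one design cell, calibrates the generating intercepts (unless
#' `params` is supplied), then for each replicate generates one pristine
#' cohort, derives each contaminated version from that same cohort (paired
#' design), fits both estimators -- log-binomial with COPY fallback and
#' robust Poisson -- to every version, and aggregates relative bias,
#' empirical SE, MSE and convergence rate per contamination level and
#' method. Only converged replicates enter the bias/SE/MSE summaries; the
#' convergence rate and the number of replicates used are reported
#' alongside.
#'
#' Replicate `r` is generated from seed `base_seed + r`, so results are
#' reproducible and individual replicates can be regenerated in isolation.
#'
#' @param scenario One row of [rr_scenarios()].
#' @param n_reps Number of Monte-Carlo replicates (default 1000).
#' @param levels Contamination levels, a subset of `c(0, 0.02, 0.05)`.
#' @param methods Estimators to fit.
#' @param copy_c Number of virtual copies for the COPY fallback.
#' @param base_seed Integer seed offset for the replicate stream.
#' @param params Optional pre-calibrated [calibrate_scenario()] result.
#' @param keep_estimates If `TRUE`, the replicate-level estimates are
#'   attached as `attr(, "estimates")` (a long data frame with columns
#'   `replicate`, `level`, `method`, `log_rr_hat`, `converged`, `used_copy`).
#' @param control An [rr_control()] list.
#' @return A data frame with one row per contamination level and method:
#'   `scenario_id`, `level`, `method`, `n_replicates`, `n_used`,
#'   `convergence_rate`, `rel_bias_pct`, `emp_se`, `mse`. The calibrated
#'   parameters are attached as `attr(, "params")`.
#' @export
run_scenario <- function(scenario, n_reps = 1000, levels = c(0, 0.02, 0.05),
                         methods = c("log_binomial", "robust_poisson"),
                         copy_c = 1e6, base_seed = 1, params = NULL,
                         keep_estimates = FALSE, control = rr_control()) {
  sc <- as.list(scenario)
  if (n_reps < 2) stop("'n_reps' must be at least 2")
  if (!all(levels %in% c(0, 0.02, 0.05)))
    stop("contamination levels must be a subset of {0, 0.02, 0.05}")
  methods <- match.arg(methods, c("log_binomial", "robust_poisson"),
                       several.ok = TRUE)
  if (is.null(params)) params <- calibrate_scenario(sc)
  n <- sc$n
  levels <- sort(levels)

  cells <- expand.grid(level = levels, method = methods,
                       stringsAsFactors = FALSE)
  est <- matrix(NA_real_, nrow = n_reps, ncol = nrow(cells))
  conv <- matrix(FALSE, nrow = n_reps, ncol = nrow(cells))
  copied <- matrix(FALSE, nrow = n_reps, ncol = nrow(cells))

  for (r in seq_len(n_reps)) {
    d <- rr_simulate(params, n, seed = base_seed + r)
    for (j in seq_len(nrow(cells))) {
      dc <- rr_contaminate(d, cells$level[j])
      X <- scenario_design_matrix(dc, params$confounder)
      fit <- if (cells$method[j] == "log_binomial")
        fit_log_binomial_X(X, dc$y, copy_c = copy_c, control = control)
      else
        fit_robust_poisson_X(X, dc$y, control = control)
      est[r, j] <- fit$coefficients[["x"]]
      conv[r, j] <- fit$converged
      copied[r, j] <- isTRUE(fit$used_copy)
    }
  }

  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(j) {
    cbind(data.frame(scenario_id = params$scenario_id,
                     level = cells$level[j], method = cells$method[j]),
          summarize_cell(est[, j], conv[, j], sc$true_rr))
  }))
  rownames(out) <- NULL
  attr(out, "params") <- params
  if (keep_estimates) {
    attr(out, "estimates") <- data.frame(
      replicate = rep(seq_len(n_reps), times = nrow(cells)),
      level = rep(cells$level, each = n_reps),
      method = rep(cells$method, each = n_reps),
      log_rr_hat = as.vector(est),
      converged = as.vector(conv),
      used_copy = as.vector(copied))
  }
  out
}

#' Run the full simulation study over a scenario grid
#'
#' Iterates [run_scenario()] over every row of a scenario grid, with a
#' disjoint, deterministic replicate seed block per scenario. Optionally
#' writes the tidy summary table, the pivoted bias/SE/MSE tables and the
#' calibrated intercepts to an output directory.
#'
#' @param scenarios A scenario grid from [rr_scenarios()] (any subset of
#'   rows).
#' @param n_reps,levels,methods,copy_c,control Passed to [run_scenario()].
#' @param base_seed Study-level seed; scenario `i` uses replicate seeds
#'   `base_seed + 10000 (i - 1) + 1 ... n_reps`.
#' @param output_dir Optional directory: writes `summary.csv` (tidy, one row
#'   per scenario x level x method), `table_bias.csv`, `table_se.csv`,
#'   `table_mse.csv` (pivoted with LB/RP columns) and `calibration.json`
#'   (calibrated intercepts per scenario, when the jsonlite package is
#'   available).
#' @param keep_estimates Attach replicate-level estimates per scenario.
#' @return A data frame of class `"rr_study"` stacking all scenario
#'   summaries, with the scenario grid in `attr(, "scenarios")` and the
#'   calibrated parameter sets in `attr(, "params")`.
#' @seealso [plot.rr_study()], [study_table()]
#' @export
run_study <- function(scenarios, n_reps = 1000, levels = c(0, 0.02, 0.05),
                      methods = c("log_binomial", "robust_poisson"),
                      copy_c = 1e6, base_seed = 1, output_dir = NULL,
                      keep_estimates = FALSE, control = rr_control()) {
  res <- vector("list", nrow(scenarios))
  prm <- vector("list", nrow(scenarios))
  estlist <- if (keep_estimates) vector("list", nrow(scenarios)) else NULL
  for (i in seq_len(nrow(scenarios))) {
    res[[i]] <- run_scenario(scenarios[i, ], n_reps = n_reps, levels = levels,
                             methods = methods, copy_c = copy_c,
                             base_seed = base_seed + 10000 * (i - 1),
                             keep_estimates = keep_estimates,
                             control = control)
    prm[[i]] <- attr(res[[i]], "params")
    if (keep_estimates) {
      e <- attr(res[[i]], "estimates")
      e$scenario_id <- prm[[i]]$scenario_id
      estlist[[i]] <- e
    }
  }
  out <- do.call(rbind, lapply(res, function(x) { attributes(x)[c("params", "estimates")] <- NULL; x }))
  rownames(out) <- NULL
  names(prm) <- vapply(prm, `[[`, "", "scenario_id")
  attr(out, "scenarios") <- scenarios
  attr(out, "params") <- prm
  if (keep_estimates) attr(out, "estimates") <- do.call(rbind, estlist)
  class(out) <- c("rr_study", "data.frame")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
    for (m in c("rel_bias_pct", "emp_se", "mse")) {
      short <- c(rel_bias_pct = "bias", emp_se = "se", mse = "mse")[[m]]
      utils::write.csv(study_table(out, m),
                       file.path(output_dir, paste0("table_", short, ".csv")),
                       row.names = FALSE)
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        lapply(prm, function(p) p[c("a0", "a1", "b0", "b1", "b2",
                                    "confounder", "exposure_rate",
                                    "outcome_rate")]),
        file.path(output_dir, "calibration.json"),
        auto_unbox = TRUE, digits = NA)
    }
  }
  out
}

#' Pivot study summaries into a publication-style table
#'
#' Reshapes the tidy study summary into one row per scenario and
#' contamination level with side-by-side columns for the log-binomial (LB)
#' and robust Poisson (RP) estimators, the layout in which bias, SE and MSE
#' results of this design are usually reported.
#'
#' @param study An `"rr_study"` result from [run_study()].
#' @param measure Which measure to tabulate: `"rel_bias_pct"`, `"emp_se"` or
#'   `"mse"`.
#' @return A data frame with columns `scenario_id`, `level`, `LB`, `RP`.
#' @export
study_table <- function(study, measure = c("rel_bias_pct", "emp_se", "mse")) {
  measure <- match.arg(measure)
  key <- unique(study[, c("scenario_id", "level")])
  pick <- function(id, lv, meth) {
    v <- study[[measure]][study$scenario_id == id & study$level == lv &
                          study$method == meth]
    if (length(v) == 1) v else NA_real_
  }
  key$LB <- mapply(pick, key$scenario_id, key$level,
                   MoreArgs = list(meth = "log_binomial"))
  key$RP <- mapply(pick, key$scenario_id, key$level,
                   MoreArgs = list(meth = "robust_poisson"))
  rownames(key) <- NULL
  key
}

#' Plot relative bias against contamination level
#'
#' Draws one panel per combination of confounder form and association
#' strength present in the study, with relative bias (%) on the vertical
#' axis and contamination level on the horizontal axis; within a panel, one
#' line per scenario and method (log-binomial: solid blue; robust Poisson:
#' dotted red).
#'
#' @param x An `"rr_study"` result from [run_study()].
#' @param ... Further arguments passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.rr_study <- function(x, ...) {
  scn <- attr(x, "scenarios")
  panels <- unique(scn[, c("confounder", "association")])
  op <- graphics::par(mfrow = grDevices::n2mfrow(nrow(panels)),
                      mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(nrow(panels))) {
    ids <- scn$scenario_id[scn$confounder == panels$confounder[i] &
                           scn$association == panels$association[i]]
    sub <- x[x$scenario_id %in% ids, ]
    lv <- sort(unique(sub$level))
    series <- expand.grid(scenario_id = ids,
                          method = unique(sub$method),
                          stringsAsFactors = FALSE)
    ymat <- sapply(seq_len(nrow(series)), function(j) {
      s <- sub[sub$scenario_id == series$scenario_id[j] &
               sub$method == series$method[j], ]
      s$rel_bias_pct[match(lv, s$level)]
    })
    is_lb <- series$method == "log_binomial"
    graphics::matplot(lv, ymat, type = "b", pch = 16,
                      lty = ifelse(is_lb, 1, 3),
                      col = ifelse(is_lb, "blue", "red"),
                      xlab = "Contamination level",
                      ylab = "Relative bias (%)",
                      main = sprintf("%s confounder, %s association",
                                     panels$confounder[i],
                                     panels$association[i]), ...)
    graphics::abline(h = 0, col = "grey70")
  }
  invisible(x)
}
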