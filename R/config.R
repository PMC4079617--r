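#' Load a study configuration from YAML or JSON
#'
#' Reads a configuration file restricting and parameterising the simulation
#' study. Recognised keys (all optional): `rr`, `outcome_rate`,
#' `association`, `form` (confounder form), `n` (sample sizes), `reps`,
#' `contamination_levels`, `copy_c`, `seed`. Unknown keys are rejected so
#' typos fail loudly.
#'
#' @param path Path to a `.yaml`/`.yml` (requires the yaml package) or
#'   `.json` (requires jsonlite) file.
#' @return A list with elements `scenarios` (the restricted grid from
#'   [rr_scenarios()]), `n_reps`, `levels`, `copy_c` and `base_seed`, ready
#'   to pass to [run_study()].
#' @export
rr_study_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the 'jsonlite' package")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config file must be .yaml, .yml or .json")

  ## YAML 1.1 parses a bare key `n` as the boolean FALSE; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  known <- c("rr", "outcome_rate", "association", "form", "n", "reps",
             "contamination_levels", "copy_c", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))

  arg <- function(key, default) if (is.null(cfg[[key]])) default else unlist(cfg[[key]])
  scenarios <- rr_scenarios(
    sample_sizes = arg("n", 1500),
    true_rr = arg("rr", RR_LEVELS),
    outcome_rate = arg("outcome_rate", OUTCOME_RATES),
    association = arg("association", ASSOC_LEVELS),
    confounder = arg("form", CONFOUNDER_FORMS))
  list(scenarios = scenarios,
       n_reps = arg("reps", 1000),
       levels = arg("contamination_levels", c(0, 0.02, 0.05)),
       copy_c = arg("copy_c", 1e6),
       base_seed = arg("seed", 1))
}
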