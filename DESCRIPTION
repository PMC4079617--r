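Package: relrisk
Title: Relative-Risk Regression for Common Binary Outcomes and Outlier-Contamination Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits the two standard model-based estimators of adjusted relative
    risks (risk ratios) for common binary outcomes: log-binomial regression by
    constrained iteratively reweighted least squares with the COPY-method
    fallback for boundary maximum-likelihood estimates, and robust (modified)
    Poisson regression with an independence-GEE sandwich variance. Also
    provides a fully seeded Monte-Carlo framework that generates cohorts with
    a Beta-distributed confounder, a logistic exposure model and a
    log-binomial outcome model calibrated to target marginal rates,
    contaminates them by flipping outcomes of records with extreme true
    outcome probabilities, and summarises relative bias, empirical standard
    error, mean square error and convergence rates of both estimators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), sandwich, jsonlite, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
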