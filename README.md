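# relrisk

Model-based estimation of adjusted **relative risks (risk ratios)** for
common binary outcomes, and a fully seeded Monte-Carlo framework for
studying how the two standard estimators behave when a small fraction of
outcomes is misrecorded (outliers at leverage points).

## The scientific problem

When a binary outcome is common (prevalence above ~10%), the odds ratio
from logistic regression overstates the relative risk, so epidemiologists
estimate the RR directly with one of two models for
`P(Y = 1 | X, Z) = p(x, z)`:

* **Log-binomial regression** — a binomial GLM with log link,

  `log p = β₀ + β₁ x + β₂ z (+ …)`,

  so `exp(β₁)` is the adjusted RR. The MLE is efficient but may sit on the
  boundary of the parameter space (fitted probability → 1), where IRLS
  fails to converge. The **COPY method** restores an (approximate) interior
  MLE: refit with weight `C` on the original data stacked with weight 1 on
  an outcome-reversed copy (`Y ↦ 1 − Y`); with `C = 10⁶` the approximation
  is accurate to well past three decimals.

* **Robust (modified) Poisson regression** — a Poisson working GLM with log
  link applied to the binary outcome. Its point estimates coincide with an
  independence-GEE fit, and the classical **sandwich variance**
  `A⁻¹ B A⁻¹` (expected-information bread `A = X'WX`, score outer-product
  meat `B = Σ (yᵢ − μᵢ)² xᵢxᵢ'`) corrects the misspecified Poisson
  variance.

Both are exposed through one fitting function, `rrfit()`, which returns a
classed object with `print`, `summary`, `coef`, `vcov`, `confint`,
`predict` and `residuals` methods.

The simulation side regenerates a contamination study: cohorts with a
`Beta(6, 2)` confounder `Z` (mean 0.75; think `100·Z` = age in an elderly
population), exposure from `logit(p_x) = a₀ + a₁ Z` calibrated to 50%
exposure, outcome from a log-binomial model (linear or quadratic in `Z`)
calibrated to a 10/25/40% marginal rate, then contaminated by flipping the
outcomes of the records with the most extreme true outcome probabilities
(2% and 5% overall). Relative bias, empirical SE, MSE and convergence rates
of both estimators are aggregated over replicates.

## Worked example

```r
library(relrisk)

# one design cell: RR = 1.5, 10% outcome rate, moderate confounding,
# quadratic confounder effect, n = 1500
sc     <- rr_scenarios(1500, true_rr = 1.5, outcome_rate = 0.10,
                       association = "moderate", confounder = "quadratic")
params <- calibrate_scenario(sc)
params
#> Calibrated generating parameters for RR1.5_P10_moderate_quadratic_n1500
#>   exposure model: logit(p_x) = -0.519918 + 0.693147 z  (marginal rate 0.500000)
#>   outcome model:  log(p_y) = -3.263463 + 0.405465 x + 0.693147 z + 0.346574 z^2  (marginal rate 0.100000)

d   <- rr_contaminate(rr_simulate(params, 1500, seed = 42), 0.02)
fit <- rrfit(y ~ x + z + I(z^2), d, method = "log_binomial")
summary(fit)
#> Log-binomial regression (n = 1500)
#> Fitted by the COPY method.
#>
#>             Estimate Std. Error z value Pr(>|z|)
#> (Intercept)   1.2939     0.1002  12.912   <2e-16 ***
#> x             0.2994     0.1365   2.193   0.0283 *
#> z           -11.3604     0.9087 -12.501   <2e-16 ***
#> I(z^2)        8.4821     0.9018   9.406   <2e-16 ***
#>
#> Adjusted RR (x): 1.3490, 95% CI [1.0324, 1.7628]
```

The true log RR is `log 1.5 = 0.405`; thirty flipped outcomes (2% of the
cohort) already pull the estimate down to 0.299 — and bend the fitted
confounder effect far from the generating curve, the leverage-point
mechanism the study quantifies.

A scenario-level summary over 100 replicates:

```r
run_scenario(sc, n_reps = 100, base_seed = 1)
#>                          scenario_id level         method ... rel_bias_pct emp_se    mse
#> 1 RR1.5_P10_moderate_quadratic_n1500  0.00   log_binomial          -5.95  0.178 0.0324
#> 2 RR1.5_P10_moderate_quadratic_n1500  0.02   log_binomial         -34.72  0.161 0.0459
#> 3 RR1.5_P10_moderate_quadratic_n1500  0.05   log_binomial         -55.77  0.149 0.0735
#> 4 RR1.5_P10_moderate_quadratic_n1500  0.00 robust_poisson          -5.96  0.179 0.0325
#> 5 RR1.5_P10_moderate_quadratic_n1500  0.02 robust_poisson         -24.55  0.156 0.0343
#> 6 RR1.5_P10_moderate_quadratic_n1500  0.05 robust_poisson         -44.66  0.127 0.0489
```

Unbiased at 0% contamination (within Monte-Carlo noise at 100 replicates),
negative bias growing with contamination, and a visibly smaller bias for the
robust Poisson model once the confounder enters quadratically — at matched
empirical SEs. `run_study()` iterates a whole grid (`rr_scenarios()` builds
all 24 cells per sample size) and writes tidy and pivoted CSV tables plus a
bias-versus-contamination plot; `rr_study_config()` reads a YAML/JSON study
configuration.

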