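# Small builders shared across test files; everything is generated in code.

# 2x2 cohort: n1 exposed with e1 events, n0 unexposed with e0 events
cohort_2x2 <- function(e1, n1, e0, n0) {
  data.frame(y = rep(c(1, 0, 1, 0), c(e1, n1 - e1, e0, n0 - e0)),
             x = rep(c(1, 0), c(n1, n0)))
}

# one calibrated scenario row by id fragments
scenario_row <- function(rr, rate, assoc, form, n = 1500) {
  sc <- rr_scenarios(n, true_rr = rr, outcome_rate = rate,
                     association = assoc, confounder = form)
  stopifnot(nrow(sc) == 1)
  sc
}
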