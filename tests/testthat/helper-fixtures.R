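# Shared fixtures: parameter sets scaled so simulated lifetimes stay short
# enough for fast, well-populated test statistics.

kBT_REF <- 4.11

# destabilized variant (high ionic strength): ~10x faster dissociation
fast_params <- function(...) {
  formin_params(salt_multiplier = 10, ...)
}

# single-route Bell truth: always-open FH2, no transition-route dissociation
bell_only_params <- function(k0 = 0.003, delta = 2.7, k_on = 22) {
  formin_params(k_on = k_on, K_co = 1e-9, k_offO0 = k0, delta_O = delta,
                k_offT0 = 0, delta_T = 0)
}

# censoring-aware exponential MLE and its standard error from a population
empirical_rate <- function(pop) {
  s <- population_summary(pop)
  horizon <- attr(pop, "horizon")
  d <- sum(!s$censored)
  total <- sum(ifelse(s$censored, horizon, s$dissociation_time))
  list(k = d / total, se = d / total / sqrt(d), n_events = d)
}
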