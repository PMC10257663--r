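# Shared fixtures: the untreated AU565-like condition (mean G1 and S-G2
# durations of 22.3 h) and the example drug profiles built on it.
fx <- lctcycle::example_profiles()

# a small heterogeneous rate set exercising part-specific rates
hetero_rates <- function() {
  rate_set(alpha = c(0.2, 0.4, 0.8, 0.4), beta = c(0.6, 1.0, 0.8, 1.2),
           gamma1 = c(0.01, 0.02, 0, 0.005), gamma2 = c(0, 0.01, 0.02, 0.01))
}

# agent-based ensemble mean per starting cell, on the default grid
ensemble_mean <- function(rates, runs, n0, g1_fraction = 0.75) {
  arr <- array(0, c(runs, 193, 3))
  for (r in seq_len(runs)) {
    rec <- simulate_cells(rates, n0 = n0, initial_g1_fraction = g1_fraction)
    pop <- bin_population(rec)
    arr[r, , 1] <- pop$g1 / n0
    arr[r, , 2] <- pop$sg2 / n0
    arr[r, , 3] <- pop$dead_cum / n0
  }
  list(mean = apply(arr, c(2, 3), mean),
       se = apply(arr, c(2, 3), sd) / sqrt(runs))
}
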