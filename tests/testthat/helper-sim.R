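# Small shared fixtures, built in code at test time.

tiny_session <- function(day = "training", n_neurons = 12, n_us = 3, n_cs = 0,
                         n_movon = 0, seed = 11L, ...) {
  sch <- build_schedule(day, seed = seed)
  beh <- simulate_behavior(sch, behavior_spec(seed = seed + 1L))
  sim <- simulate_population(sch, beh, population_spec(
    n_neurons = n_neurons, n_us_responders = n_us, n_cs_responders = n_cs,
    n_movon_responders = n_movon, seed = seed + 2L, ...
  ))
  list(schedule = sch, behavior = beh, traceset = sim$traceset,
       gt = sim$ground_truth)
}

# AR(1) impulse response trace with planted jump times/amplitudes.
ar1_trace <- function(n, gamma, jumps, amps, noise_sd = 0, baseline = 0,
                      seed = 1L) {
  s <- numeric(n)
  s[jumps] <- amps
  c0 <- as.numeric(stats::filter(s, gamma, method = "recursive"))
  if (noise_sd > 0) {
    set.seed(seed)
    c0 <- c0 + rnorm(n, 0, noise_sd)
  }
  baseline + c0
}
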