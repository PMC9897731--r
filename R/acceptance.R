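#' Planted-count benchmark worlds
#'
#' Builds one of three benchmark sessions whose planted responder counts
#' equal published population tallies (45/163 and 79/201 footshock
#' responders on the training day; 6/176 tone responders on the habituation
#' day), runs the full pipeline (deconvolution, Z-scoring, event alignment,
#' classification) and returns the recovered count. Footshock responses are
#' planted at 5x the trace noise SD, tone responses at 3x, background events
#' at 0.02 events/s in both movement states; SNR and rates are part of the
#' benchmark definition, not tuning knobs.
#'
#' @param id `"t1"` (163 neurons, 45 footshock responders), `"t2"` (201 / 79)
#'   or `"t3"` (176 neurons, 6 tone responders).
#' @param seed integer master seed.
#' @return list: `value` (recovered responder count), `n` (neurons
#'   simulated), `planted`, `kind`, `day`.
#' @export
planted_count_benchmark <- function(id = c("t1", "t2", "t3"), seed = 1L) {
  id <- match.arg(id)
  setup <- switch(id,
    t1 = list(day = "training", n = 163L, n_us = 45L, n_cs = 0L,
              amp = 5, kind = "US"),
    t2 = list(day = "training", n = 201L, n_us = 79L, n_cs = 0L,
              amp = 5, kind = "US"),
    t3 = list(day = "habituation", n = 176L, n_us = 0L, n_cs = 6L,
              amp = 3, kind = "CS_beep")
  )
  seed <- as.integer(seed)
  schedule <- build_schedule(setup$day, seed = seed)
  behavior <- simulate_behavior(schedule, behavior_spec(seed = seed + 1L))
  sim <- simulate_population(schedule, behavior, population_spec(
    n_neurons = setup$n, n_us_responders = setup$n_us,
    n_cs_responders = setup$n_cs, response_amplitude = setup$amp,
    response_latency = 0.1, background_rate_moving = 0.02,
    background_rate_freezing = 0.02, duplicate_fraction = 0,
    seed = seed + 2L
  ))
  res <- analyze_session(sim$traceset, schedule, behavior, dedup = FALSE)
  tab <- res$responders
  value <- sum(tab$responder[tab$kind == setup$kind])
  planted <- if (setup$kind == "US") setup$n_us else setup$n_cs
  list(value = value, n = setup$n, planted = planted,
       kind = setup$kind, day = setup$day)
}
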