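test_that("schedules satisfy the protocol invariants", {
  hab <- build_schedule("habituation", seed = 1)
  expect_equal(nrow(hab$block_intervals), 6)
  expect_length(hab$beep_onsets, 180)
  expect_length(hab$us_onsets, 0)

  rec <- build_schedule("recall", seed = 1)
  expect_equal(nrow(rec$block_intervals), 4)
  expect_length(rec$us_onsets, 0)

  trn <- build_schedule("training", seed = 5)
  expect_length(trn$us_onsets, 6)
  expect_equal(trn$us_onsets, trn$block_intervals$end)
  expect_equal(trn$us_duration, 1)
  gaps <- trn$block_intervals$start[-1] - trn$block_intervals$end[-6]
  expect_true(all(gaps >= 60 & gaps <= 120))

  for (sch in list(hab, rec, trn)) {
    # beeps at 1 Hz within each block, all events inside the session
    expect_equal(unname(diff(sch$beep_onsets)[1:29]), rep(1, 29))
    expect_true(all(sch$beep_onsets < sch$session_length))
    expect_true(all(sch$block_intervals$end < sch$session_length))
    blk <- findInterval(sch$beep_onsets, sch$block_intervals$start)
    expect_equal(as.vector(table(blk)), rep(30L, nrow(sch$block_intervals)))
  }

  expect_error(build_schedule("retrieval"), class = "vtsfear_invalid_argument")
})

test_that("behavior generator is deterministic and honors bout statistics", {
  sch <- build_schedule("habituation", seed = 2)
  b1 <- simulate_behavior(sch, behavior_spec(seed = 9))
  b2 <- simulate_behavior(sch, behavior_spec(seed = 9))
  expect_identical(b1, b2)
  b3 <- simulate_behavior(sch, behavior_spec(seed = 10))
  expect_false(identical(b1$movement_index, b3$movement_index))
  expect_length(b1$movement_index, floor(sch$session_length * 30))

  # freezing disabled -> downstream freezing is 0% of frames
  b0 <- simulate_behavior(sch, behavior_spec(mean_freeze_bout = 0, seed = 3))
  expect_true(all(b0$state == 1L))
  fz <- detect_freezing(b0$movement_index, 30)
  expect_equal(sum(fz), 0)

  # law of large numbers on the bout sampler: ~10^4 s of simulation
  long <- structure(list(
    day_kind = "habituation", beep_onsets = numeric(0),
    block_intervals = data.frame(start = numeric(0), end = numeric(0)),
    us_onsets = numeric(0), us_duration = 0, session_length = 10000
  ), class = "ExperimentSchedule")
  bl <- simulate_behavior(long, behavior_spec(mean_freeze_bout = 3, seed = 4))
  r <- rle(bl$state)
  bouts <- r$lengths[r$values == 0L] / 30
  expect_gt(length(bouts), 100)
  expect_lt(abs(mean(bouts) - 3) / 3, 0.1)
})

test_that("population generator plants the requested structure", {
  s <- tiny_session(n_neurons = 10, n_us = 2, n_cs = 1, seed = 21)
  gt <- s$gt
  expect_equal(sum(gt$labels$us), 2)
  expect_equal(sum(gt$labels$cs), 1)
  expect_equal(sum(gt$labels$movon), 0)
  # every US responder carries one event per US at the planted latency
  for (i in which(gt$labels$us)) {
    ev <- gt$events[gt$events$neuron == i, ]
    expect_true(all((s$schedule$us_onsets + 0.1) %in% ev$time))
  }
  expect_error(
    population_spec(n_neurons = 5, n_us_responders = 6),
    class = "vtsfear_invalid_argument"
  )

  # all rates zero, no responders -> pure noise, empty ground truth
  s0 <- tiny_session(n_neurons = 10, n_us = 0,
                     background_rate_moving = 0, background_rate_freezing = 0,
                     seed = 22)
  expect_equal(nrow(s0$gt$events), 0)
  centered <- sweep(s0$traceset$traces, 1, rowMeans(s0$traceset$traces))
  expect_true(all(abs(centered) < 6)) # pure N(0,1) noise around baseline

  # determinism
  sa <- tiny_session(seed = 23)
  sb <- tiny_session(seed = 23)
  expect_identical(sa$traceset, sb$traceset)
  expect_identical(sa$gt, sb$gt)
})

test_that("noiseless traces equal the kernel convolution of planted events", {
  s <- tiny_session(n_neurons = 6, n_us = 2, n_cs = 1, noise_sd = 0, seed = 31,
                    background_rate_moving = 0.05, background_rate_freezing = 0.05)
  rate <- s$traceset$rate
  n_t <- ncol(s$traceset$traces)
  for (i in seq_len(6)) {
    ev <- s$gt$events[s$gt$events$neuron == i, ]
    ref <- vtsfear:::events_to_trace(ev$time, ev$amplitude, n_t, rate, 1.0)
    got <- s$traceset$traces[i, ] - mean(s$traceset$traces[i, ] - ref)
    scale <- max(1, max(abs(ev$amplitude), 0))
    expect_lt(max(abs(got - ref)) / scale, 1e-9)
  }
})

test_that("duplicates are injective copies on another plane within 20 um", {
  s <- tiny_session(n_neurons = 10, n_us = 0, duplicate_fraction = 0.3,
                    seed = 41)
  dm <- s$gt$duplicate_map
  expect_equal(nrow(dm), 3)
  expect_false(anyDuplicated(dm$copy) > 0)
  expect_equal(nrow(s$traceset$traces), 13)
  d <- sqrt(rowSums((s$traceset$coords[dm$original, , drop = FALSE] -
                       s$traceset$coords[dm$copy, , drop = FALSE])^2))
  expect_true(all(d < 20))
  expect_true(all(s$traceset$plane[dm$original] != s$traceset$plane[dm$copy]))
})

test_that("EPSC generator follows the planted Hill saturation", {
  pars <- synapse_params(max_amp = 6, i50 = 0.15, noise_sd = 0)
  recs <- simulate_epsc(c(0, 0.05, 0.15, 0.5, 1), pars, seed = 3)
  # intensity 0 -> flat trace
  expect_lt(max(abs(recs[[1]]$current)), 1e-12)
  # intensity >> i50 -> peak within 5% of max amplitude
  peak_hi <- max(abs(recs[[5]]$current))
  expect_lt(abs(peak_hi - 6) / 6, 0.05)
  # half-saturation intensity -> half amplitude
  expect_lt(abs(max(abs(recs[[3]]$current)) - 3) / 3, 0.01)
  expect_error(synapse_params(tau_rise = -1), class = "vtsfear_invalid_argument")
  expect_error(simulate_epsc(c(0.5, 0.1), pars), class = "vtsfear_invalid_argument")
})
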