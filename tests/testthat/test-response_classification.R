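test_that("align_events averages peri-event snippets exactly", {
  set.seed(4)
  z <- matrix(rnorm(2 * 400), 2)
  # single event: snippet equals the raw segment
  al <- align_events(z, 10, 12.0, window = c(-2, 4))
  expect_equal(al$n_events, 1)
  expect_equal(al$mean_z[1, ], z[1, 121 + (-20:39)])
  # two identical events average to either snippet
  al2 <- align_events(z, 10, c(12.0, 12.0), window = c(-2, 4))
  expect_equal(al2$mean_z, al$mean_z)
  # events near the edges are dropped and counted
  al3 <- align_events(z, 10, c(0.5, 12, 39.9), window = c(-2, 4))
  expect_equal(al3$n_events, 1)
  expect_equal(al3$n_dropped, 2)
  expect_error(align_events(z, 10, c(0.5), window = c(-2, 4)),
               class = "vtsfear_degenerate_input")
})

test_that("responder thresholds are applied strictly at the boundary", {
  # constant Z traces make the mean-window Z exact
  mk <- function(v) {
    z <- matrix(v, 1, 100)
    align_events(z, 10, 3, window = c(-2, 4))
  }
  tab_hi <- classify_responders(list(US = mk(1.001)), day = "training")
  tab_lo <- classify_responders(list(US = mk(0.999)), day = "training")
  expect_true(tab_hi$responder)
  expect_false(tab_lo$responder)
  tab_cs <- classify_responders(list(CS_beep = mk(0.21), movON_CS = mk(0.19)))
  expect_equal(tab_cs$responder, c(TRUE, FALSE))
  # threshold monotonicity: raising thresholds never adds responders
  set.seed(8)
  z <- matrix(rnorm(30 * 500, 0.5), 30)
  al <- list(US = align_events(z, 10, c(10, 20, 30), window = c(-2, 4)))
  n_def <- sum(classify_responders(al)$responder)
  n_hi <- sum(classify_responders(
    al, criteria = list(US = list(window = c(0, 1), threshold = 2)))$responder)
  expect_lte(n_hi, n_def)
})

test_that("pipeline recovers planted responder counts on a fixed seed", {
  s <- tiny_session(n_neurons = 40, n_us = 8, n_cs = 6, seed = 77,
                    background_rate_moving = 0.02,
                    background_rate_freezing = 0.02)
  # dedup off: the criterion pipeline is deconvolve -> z-score -> align ->
  # classify, and random coordinate draws can place two co-active planted
  # cells within the duplicate gates (see the vignette's limitations)
  res <- analyze_session(s$traceset, s$schedule, s$behavior, dedup = FALSE)
  tab <- res$responders
  expect_equal(sum(tab$responder[tab$kind == "US"]), 8)
  expect_equal(sum(tab$responder[tab$kind == "CS_beep"]), 6)
  expect_setequal(tab$neuron[tab$kind == "US" & tab$responder],
                  which(s$gt$labels$us))
  # planted 5-sigma US responses: mean Z in [0,1] s comfortably above 1
  z_us <- tab$mean_window_z[tab$kind == "US" &
                              tab$neuron %in% which(s$gt$labels$us)]
  expect_true(all(z_us > 1))
})

test_that("confound exclusion removes coupled beeps and movement-ONs", {
  ex0 <- exclude_confounded(c(10, 20), c(15, 25), 0.5)
  expect_equal(ex0$clean_beeps, c(10, 20))
  expect_equal(ex0$clean_movons, c(15, 25))
  ex1 <- exclude_confounded(c(10.0, 20), c(10.3, 25), 0.5)
  expect_equal(ex1$clean_beeps, 20)
  expect_equal(ex1$clean_movons, 25)
  expect_error(exclude_confounded(1, 2, -0.1), class = "vtsfear_invalid_argument")
  # Poisson thinning: expected excluded beep fraction ~ 1 - exp(-r*w)
  set.seed(12)
  r <- 0.4; w <- 0.5
  fracs <- replicate(40, {
    movons <- cumsum(rexp(3000, r))
    beeps <- seq(10, max(movons) - 10, by = 7)
    exclude_confounded(beeps, movons, w)$frac_beeps_excluded
  })
  expect_lt(abs(mean(fracs) - (1 - exp(-r * w))), 0.01)
})

test_that("duplicate removal applies both gates and keeps one survivor", {
  mk_ts <- function(d_um, rho, n = 3000) {
    set.seed(5)
    shared <- ar1_trace(n, 0.9, jumps = seq(20, n - 20, by = 25), amps = 5)
    t1 <- 100 + shared + rnorm(n, 0, sd(shared) * sqrt(1 / rho - 1) / sqrt(2))
    t2 <- 70 + shared + rnorm(n, 0, sd(shared) * sqrt(1 / rho - 1) / sqrt(2))
    vtsfear:::new_traceset(rbind(t1, t2),
                           rbind(c(0, 0), c(d_um, 0)), c(1L, 2L), 10)
  }
  # close + correlated: the dimmer copy (row 2) goes
  ts <- mk_ts(10, 0.9)
  out <- remove_duplicates(ts)
  expect_equal(out$removed, 2L)
  expect_equal(nrow(out$traceset$traces), 1)
  # distance gate
  out25 <- remove_duplicates(mk_ts(25, 0.9))
  expect_length(out25$removed, 0)
  # correlation gate: uncorrelated noise traces at 5 um
  set.seed(6)
  ts_lo <- vtsfear:::new_traceset(
    rbind(100 + rnorm(3000), 70 + rnorm(3000)),
    rbind(c(0, 0), c(5, 0)), c(1L, 2L), 10
  )
  expect_length(remove_duplicates(ts_lo)$removed, 0)
  # chains: three stacked copies on three planes -> one survivor
  set.seed(7)
  shared <- ar1_trace(3000, 0.9, jumps = seq(20, 2980, by = 20), amps = 8)
  tr <- rbind(100 + shared + rnorm(3000, 0, 1),
              90 + shared + rnorm(3000, 0, 1),
              80 + shared + rnorm(3000, 0, 1))
  ts3 <- vtsfear:::new_traceset(tr, rbind(c(0, 0), c(8, 0), c(16, 0)),
                                1:3, 10)
  out3 <- remove_duplicates(ts3)
  expect_equal(sort(out3$removed), c(2L, 3L))
  # soundness: no violating cross-plane pair remains
  z <- t(apply(out3$traceset$traces, 1, zscore_trace))
  expect_equal(nrow(out3$traceset$traces), 1)
})

test_that("dedup integrates with the generator's duplicate machinery", {
  s <- tiny_session(n_neurons = 12, n_us = 0, duplicate_fraction = 0.25,
                    background_rate_moving = 2, background_rate_freezing = 2,
                    seed = 55)
  out <- remove_duplicates(s$traceset)
  # every generated copy is removed (signal-dominated traces correlate > 0.7)
  expect_setequal(out$removed, s$gt$duplicate_map$copy)
})
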