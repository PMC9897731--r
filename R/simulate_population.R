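#' Parameters of the synthetic neural-population generator
#'
#' Describes a population of imaged neurons with planted, trigger-locked
#' responses. Designated responder subsets carry one calcium event per
#' matching trigger (each footshock onset, each tone beep, or each
#' freezing-to-moving transition) at a fixed latency and amplitude; all
#' neurons additionally emit background events as a state-dependent Poisson
#' process. Fluorescence is the event train convolved with a single
#' exponential (AR(1)) kernel plus i.i.d. Gaussian noise on a per-neuron
#' baseline.
#'
#' @param n_neurons number of distinct neurons (before duplication).
#' @param n_us_responders,n_cs_responders,n_movon_responders planted responder
#'   counts; the three subsets are disjoint, so their sum must not exceed
#'   `n_neurons`.
#' @param response_amplitude planted event amplitude in multiples of
#'   `noise_sd`.
#' @param response_latency s between trigger onset and the planted event.
#' @param background_rate_moving,background_rate_freezing background event
#'   rates (events/s) while the animal moves or freezes. Background
#'   amplitudes are drawn uniformly on 1-3 x `noise_sd`.
#' @param kernel_decay exponential decay time constant of the fluorescence
#'   kernel, s.
#' @param noise_sd Gaussian noise SD of the traces, a.u.
#' @param duplicate_fraction fraction of neurons additionally imaged on a
#'   second focal plane (same event train, independent noise, dimmer
#'   baseline, coordinates jittered by < 20 um).
#' @param rate calcium sampling rate per focal plane, Hz.
#' @param seed integer seed.
#' @return list of class `PopulationSpec`.
#' @export
population_spec <- function(n_neurons = 100, n_us_responders = 0,
                            n_cs_responders = 0, n_movon_responders = 0,
                            response_amplitude = 5, response_latency = 0.1,
                            background_rate_moving = 0.03,
                            background_rate_freezing = 0.01,
                            kernel_decay = 1.0, noise_sd = 1.0,
                            duplicate_fraction = 0, rate = 10, seed = 1L) {
  check_number(n_neurons, "n_neurons", 1)
  for (nm in c("n_us_responders", "n_cs_responders", "n_movon_responders")) {
    v <- get(nm)
    check_number(v, nm, 0)
    if (v > n_neurons) stop_invalid(nm, " exceeds n_neurons")
  }
  if (n_us_responders + n_cs_responders + n_movon_responders > n_neurons) {
    stop_invalid("responder counts must sum to at most n_neurons (subsets are disjoint)")
  }
  check_number(response_amplitude, "response_amplitude", 0)
  check_number(response_latency, "response_latency", 0)
  check_number(background_rate_moving, "background_rate_moving", 0)
  check_number(background_rate_freezing, "background_rate_freezing", 0)
  check_number(kernel_decay, "kernel_decay", 1e-9)
  check_number(noise_sd, "noise_sd", 0)
  check_number(duplicate_fraction, "duplicate_fraction", 0, 1)
  check_number(rate, "rate", 1e-9)
  structure(as.list(environment()), class = "PopulationSpec")
}

#' Simulate fluorescence traces with planted ground truth
#'
#' @param schedule an [build_schedule()] result covering the session.
#' @param behavior a [simulate_behavior()] result for the same session.
#' @param spec a [population_spec()].
#' @return list with elements `traceset` (a `TraceSet`: `traces`
#'   neurons x time matrix in a.u., `coords` neurons x 2 in um, `plane`,
#'   `rate`, `ids`) and `ground_truth` (`events` data.frame
#'   `neuron`,`time`,`amplitude`; `labels` data.frame with logical
#'   `us`,`cs`,`movon` per neuron; `duplicate_map` data.frame
#'   `original`,`copy`).
#' @export
simulate_population <- function(schedule, behavior, spec = population_spec()) {
  validate_schedule(schedule)
  if (!inherits(behavior, "BehaviorTrace")) stop_invalid("expected a BehaviorTrace")
  if (!inherits(spec, "PopulationSpec")) stop_invalid("expected a PopulationSpec")
  if (tail(behavior$time, 1) < schedule$session_length - 2.5 / behavior$frame_rate) {
    stop_invalid("behavior trace does not cover the schedule")
  }

  n <- spec$n_neurons
  rate <- spec$rate
  n_t <- floor(schedule$session_length * rate)
  t_grid <- (seq_len(n_t) - 1) / rate
  gamma <- exp(-1 / (rate * spec$kernel_decay))

  # behavioral state at each calcium sample (nearest video frame)
  frame_of <- pmin(length(behavior$state),
                   pmax(1L, round(t_grid * behavior$frame_rate) + 1L))
  moving <- behavior$state[frame_of] == 1L
  movon_times <- state_movement_on_times(behavior)

  with_seed(spec$seed, {
    perm <- sample.int(n)
    us_ids <- perm[seq_len(spec$n_us_responders)]
    cs_ids <- perm[spec$n_us_responders + seq_len(spec$n_cs_responders)]
    movon_ids <- perm[spec$n_us_responders + spec$n_cs_responders +
                        seq_len(spec$n_movon_responders)]

    amp <- spec$response_amplitude * spec$noise_sd
    lat <- spec$response_latency
    ev_list <- vector("list", n)
    for (i in seq_len(n)) {
      times <- numeric(0)
      amps <- numeric(0)
      if (i %in% us_ids && length(schedule$us_onsets)) {
        times <- c(times, schedule$us_onsets + lat)
        amps <- c(amps, rep(amp, length(schedule$us_onsets)))
      }
      if (i %in% cs_ids && length(schedule$beep_onsets)) {
        times <- c(times, schedule$beep_onsets + lat)
        amps <- c(amps, rep(amp, length(schedule$beep_onsets)))
      }
      if (i %in% movon_ids && length(movon_times)) {
        times <- c(times, movon_times + lat)
        amps <- c(amps, rep(amp, length(movon_times)))
      }
      # background: per-sample Poisson thinning at the state-dependent rate
      lam <- ifelse(moving, spec$background_rate_moving,
                    spec$background_rate_freezing) / rate
      cnt <- rpois(n_t, lam)
      if (any(cnt > 0)) {
        reps <- rep.int(seq_len(n_t), cnt)
        bg_t <- t_grid[reps] + runif(length(reps), 0, 1 / rate)
        bg_a <- runif(length(reps), 1, 3) * spec$noise_sd
        times <- c(times, bg_t)
        amps <- c(amps, bg_a)
      }
      keep <- times < schedule$session_length - 1 / rate
      o <- order(times[keep])
      ev_list[[i]] <- data.frame(time = times[keep][o], amplitude = amps[keep][o])
    }

    baseline <- runif(n, 80, 120)
    signal <- matrix(0, n, n_t)
    for (i in seq_len(n)) {
      signal[i, ] <- events_to_trace(ev_list[[i]]$time, ev_list[[i]]$amplitude,
                                     n_t, rate, spec$kernel_decay)
    }
    traces <- signal + baseline +
      matrix(rnorm(n * n_t, 0, spec$noise_sd), n, n_t)
    coords <- cbind(x = runif(n, -150, 150), y = runif(n, -150, 150))
    plane <- ((seq_len(n) - 1L) %% 3L) + 1L

    n_dup <- round(spec$duplicate_fraction * n)
    dup_src <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
    if (n_dup > 0) {
      dup_traces <- signal[dup_src, , drop = FALSE] + 0.7 * baseline[dup_src] +
        matrix(rnorm(n_dup * n_t, 0, spec$noise_sd), n_dup, n_t)
      dup_coords <- coords[dup_src, , drop = FALSE] +
        matrix(runif(2 * n_dup, -9, 9), n_dup, 2)
      traces <- rbind(traces, dup_traces)
      coords <- rbind(coords, dup_coords)
      plane <- c(plane, (plane[dup_src] %% 3L) + 1L)
    }

    labels <- data.frame(
      neuron = seq_len(n),
      us = seq_len(n) %in% us_ids,
      cs = seq_len(n) %in% cs_ids,
      movon = seq_len(n) %in% movon_ids
    )
    gt_events <- if (n > 0) {
      cbind(neuron = rep(seq_len(n), vapply(ev_list, nrow, 1L)),
            do.call(rbind, ev_list))
    } else {
      data.frame(neuron = integer(0), time = numeric(0), amplitude = numeric(0))
    }
    dup_map <- data.frame(original = dup_src,
                          copy = if (n_dup > 0) n + seq_len(n_dup) else integer(0))

    list(
      traceset = new_traceset(traces, coords, plane, rate),
      ground_truth = list(events = gt_events, labels = labels,
                          duplicate_map = dup_map, ar1_gamma = gamma)
    )
  })
}

# Exact discrete transient: amplitude a placed at the first sample at or
# after the event time, decayed by the sub-sample offset, then AR(1)
# recursion. This is the kernel-convolution ground truth the tests check
# against.
events_to_trace <- function(times, amps, n_t, rate, tau) {
  s <- numeric(n_t)
  if (length(times)) {
    k <- ceiling(times * rate - 1e-9) + 1L
    ok <- k >= 1L & k <= n_t
    dec <- exp(-(((k - 1) / rate) - times) / tau)
    for (j in which(ok)) s[k[j]] <- s[k[j]] + amps[j] * dec[j]
  }
  as.numeric(stats::filter(s, exp(-1 / (rate * tau)), method = "recursive"))
}

new_traceset <- function(traces, coords, plane, rate, ids = seq_len(nrow(traces))) {
  stopifnot(nrow(traces) == nrow(coords), nrow(traces) == length(plane))
  structure(list(
    traces = traces, coords = coords, plane = as.integer(plane),
    rate = rate, ids = ids
  ), class = "TraceSet")
}

#' @export
print.TraceSet <- function(x, ...) {
  cat(sprintf("<TraceSet> %d neurons x %d samples @ %g Hz, %d focal plane(s)\n",
              nrow(x$traces), ncol(x$traces), x$rate, length(unique(x$plane))))
  invisible(x)
}
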