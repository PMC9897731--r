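#' Parameters of the synthetic movement-index generator
#'
#' The behavioral model is a two-state semi-Markov chain (moving vs freezing)
#' with geometric frame-wise bout lengths, emitting a noisy movement index at
#' video rate. Defaults describe a mouse that moves most of the time with
#' occasional ~2 s freezing bouts; `cs_freeze_bias` shifts the hazard of
#' entering (and staying in) the freezing state during CS blocks, emulating
#' conditioned freezing.
#'
#' @param frame_rate video frame rate, Hz.
#' @param mean_move_bout,mean_freeze_bout mean bout durations, s.
#'   `mean_freeze_bout = 0` disables freezing entirely.
#' @param move_level,freeze_level movement-index levels (a.u.) emitted in each
#'   state; with the default freezing-detection threshold of 40 a.u. the
#'   defaults put moving frames far above and freezing frames far below it.
#' @param index_noise_sd Gaussian noise SD of the index, a.u.
#' @param cs_freeze_bias multiplicative shift (>= 0) applied during CS blocks:
#'   the moving-to-freezing hazard is scaled by `1 + cs_freeze_bias` and the
#'   freezing-to-moving hazard by `1/(1 + cs_freeze_bias)`.
#' @param seed integer seed.
#' @return list of class `BehaviorSpec`.
#' @export
behavior_spec <- function(frame_rate = 30, mean_move_bout = 10,
                          mean_freeze_bout = 2, move_level = 200,
                          freeze_level = 10, index_noise_sd = 8,
                          cs_freeze_bias = 0, seed = 1L) {
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(mean_move_bout, "mean_move_bout", lower = 1e-9)
  check_number(mean_freeze_bout, "mean_freeze_bout", lower = 0)
  check_number(move_level, "move_level", lower = 0)
  check_number(freeze_level, "freeze_level", lower = 0)
  check_number(index_noise_sd, "index_noise_sd", lower = 0)
  check_number(cs_freeze_bias, "cs_freeze_bias", lower = 0)
  structure(list(
    frame_rate = frame_rate, mean_move_bout = mean_move_bout,
    mean_freeze_bout = mean_freeze_bout, move_level = move_level,
    freeze_level = freeze_level, index_noise_sd = index_noise_sd,
    cs_freeze_bias = cs_freeze_bias, seed = as.integer(seed)
  ), class = "BehaviorSpec")
}

#' Simulate a movement-index trace for one session
#'
#' Runs the two-state chain of [behavior_spec()] over the session defined by
#' `schedule` and emits the per-frame movement index plus the hidden state as
#' ground truth.
#'
#' @param schedule an [build_schedule()] result.
#' @param spec a [behavior_spec()].
#' @return `BehaviorTrace`: list with `movement_index` (a.u. per frame),
#'   `state` (1 = moving, 0 = freezing; ground truth), `frame_rate`, and
#'   `time` (s, frame start times).
#' @export
simulate_behavior <- function(schedule, spec = behavior_spec()) {
  validate_schedule(schedule)
  if (!inherits(spec, "BehaviorSpec")) stop_invalid("expected a BehaviorSpec")
  fr <- spec$frame_rate
  n <- floor(schedule$session_length * fr)
  t <- (seq_len(n) - 1) / fr
  in_cs <- in_intervals(t, schedule$block_intervals$start, schedule$block_intervals$end)

  p_mf0 <- if (spec$mean_freeze_bout <= 0) 0 else 1 / (spec$mean_move_bout * fr)
  p_fm0 <- if (spec$mean_freeze_bout <= 0) 1 else 1 / (spec$mean_freeze_bout * fr)
  bias <- 1 + spec$cs_freeze_bias

  with_seed(spec$seed, {
    u <- runif(n)
    state <- integer(n)
    s <- 1L # start moving
    for (i in seq_len(n)) {
      p_mf <- min(1, if (in_cs[i]) p_mf0 * bias else p_mf0)
      p_fm <- min(1, if (in_cs[i]) p_fm0 / bias else p_fm0)
      if (s == 1L) {
        if (u[i] < p_mf) s <- 0L
      } else {
        if (u[i] < p_fm) s <- 1L
      }
      state[i] <- s
    }
    level <- ifelse(state == 1L, spec$move_level, spec$freeze_level)
    idx <- pmax(0, level + rnorm(n, 0, spec$index_noise_sd))
    structure(list(
      movement_index = idx, state = state, frame_rate = fr, time = t
    ), class = "BehaviorTrace")
  })
}

#' @export
print.BehaviorTrace <- function(x, ...) {
  cat(sprintf(
    "<BehaviorTrace> %d frames @ %g Hz, %.1f%% frames in freezing state\n",
    length(x$movement_index), x$frame_rate, 100 * mean(x$state == 0)
  ))
  invisible(x)
}

# Ground-truth state transition times (freezing -> moving), s.
state_movement_on_times <- function(behavior) {
  d <- diff(behavior$state)
  behavior$time[which(d == 1L) + 1L]
}
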