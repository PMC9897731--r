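#' Label every analyzed frame with its CS x movement state combination
#'
#' Partitions the session into the four combinations Frz_noCS, Mov_noCS,
#' Frz_CS, Mov_CS on the behavior clock. CS applies within the 30 s tone
#' blocks (half-open intervals). On sessions with footshocks, frames from 1 s
#' before each US onset to 1 s after its offset are excluded from the
#' labeling by default (shock artifacts are neither a movement nor a CS
#' state); excluded frames carry `NA`.
#'
#' @param freezing binary freezing trace (per frame).
#' @param frame_rate frames per second.
#' @param schedule the session's [build_schedule()] result.
#' @param exclude_us exclude the padded footshock periods.
#' @param us_pad padding around each US, s.
#' @return list with `labels` (factor per frame, levels Frz_noCS, Mov_noCS,
#'   Frz_CS, Mov_CS, `NA` for excluded frames) and `durations` (named
#'   numeric, s, including an `excluded` entry).
#' @export
label_state_intervals <- function(freezing, frame_rate, schedule,
                                  exclude_us = TRUE, us_pad = 1) {
  validate_schedule(schedule)
  n <- length(freezing)
  t <- (seq_len(n) - 1) / frame_rate
  if (abs(n / frame_rate - schedule$session_length) > 2 / frame_rate + 1e-9) {
    stop_invalid("behavior trace and schedule are on different session clocks")
  }
  bl <- schedule$block_intervals
  cs <- in_intervals(t, bl$start, bl$end)
  lv <- c("Frz_noCS", "Mov_noCS", "Frz_CS", "Mov_CS")
  lab <- ifelse(cs,
                ifelse(freezing == 1L, "Frz_CS", "Mov_CS"),
                ifelse(freezing == 1L, "Frz_noCS", "Mov_noCS"))
  if (exclude_us && length(schedule$us_onsets)) {
    excl <- in_intervals(t, schedule$us_onsets - us_pad,
                         schedule$us_onsets + schedule$us_duration + us_pad)
    lab[excl] <- NA
  }
  labels <- factor(lab, levels = lv)
  dur <- as.numeric(table(labels)) / frame_rate
  names(dur) <- lv
  dur["excluded"] <- sum(is.na(labels)) / frame_rate
  list(labels = labels, durations = dur, frame_rate = frame_rate)
}

#' Amplitude-weighted event frequency per state combination
#'
#' For each neuron and each CS x movement combination, sums the
#' sigma-normalized amplitudes of the deconvolved calcium events falling in
#' that combination's frames and divides by the combination's total duration.
#' Combinations with zero duration are reported `NA`. Events are assigned by
#' the label of the video frame containing them (half-open frames), so each
#' event is counted exactly once.
#'
#' @param events data.frame `neuron`, `time` (s), `amplitude` (sigma units),
#'   e.g. from [deconvolve_traceset()].
#' @param state a [label_state_intervals()] result.
#' @param neurons neuron ids to report (defaults to those present in
#'   `events`).
#' @param day optional session label column.
#' @return `StateActivity` data.frame: `neuron`, `day`, `state`,
#'   `freq_sigma_per_s`, `duration_s`.
#' @export
amplitude_weighted_frequency <- function(events, state, neurons = NULL,
                                         day = NA_character_) {
  lv <- levels(state$labels)
  if (is.null(neurons)) neurons <- sort(unique(events$neuron))
  frame <- pmin(length(state$labels),
                pmax(1L, floor(events$time * state$frame_rate + 1e-9) + 1L))
  ev_lab <- state$labels[frame]
  out <- expand.grid(neuron = neurons, state = lv, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$day <- day
  out$duration_s <- state$durations[out$state]
  out$freq_sigma_per_s <- NA_real_
  for (r in seq_len(nrow(out))) {
    if (out$duration_s[r] > 0) {
      sel <- events$neuron == out$neuron[r] & !is.na(ev_lab) &
        ev_lab == out$state[r]
      out$freq_sigma_per_s[r] <- sum(events$amplitude[sel]) / out$duration_s[r]
    }
  }
  out <- out[, c("neuron", "day", "state", "freq_sigma_per_s", "duration_s")]
  class(out) <- c("StateActivity", "data.frame")
  out
}
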