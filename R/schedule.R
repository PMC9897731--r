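#' Build a session schedule for the three-day fear-conditioning protocol
#'
#' Constructs the timed stimulus layout of one session. Habituation: six 30 s
#' tone (CS) blocks of 30 beeps at 1 Hz, blocks 90 s apart. Training: six CS
#' blocks pseudo-randomly spaced 60-120 s apart, each block immediately
#' followed by a 1 s footshock (US). Recall: four CS blocks, no US, 90 s
#' apart (in a different context; the context switch has no timing
#' consequence).
#'
#' @param day_kind one of `"habituation"`, `"training"`, `"recall"`.
#' @param seed integer seed; only the training-day inter-block gaps are
#'   random (uniform on \[60, 120\] s).
#' @param lead_in,lead_out quiet time (s) before the first and after the last
#'   stimulus.
#' @return An object of class `ExperimentSchedule`: list with `day_kind`,
#'   `beep_onsets` (s), `block_intervals` (data.frame `start`,`end`),
#'   `us_onsets` (s), `us_duration` (s), `session_length` (s).
#' @examples
#' sch <- build_schedule("habituation", seed = 1)
#' length(sch$beep_onsets)  # 180 beeps
#' @export
build_schedule <- function(day_kind = c("habituation", "training", "recall"),
                           seed = 1L, lead_in = 60, lead_out = 60) {
  if (!is.character(day_kind) || !day_kind[1] %in% c("habituation", "training", "recall")) {
    stop_invalid("unknown day_kind: ", day_kind[1])
  }
  day_kind <- day_kind[1]
  check_number(lead_in, "lead_in", 0)
  check_number(lead_out, "lead_out", 0)

  n_blocks <- switch(day_kind, habituation = 6L, training = 6L, recall = 4L)
  block_len <- 30
  gaps <- switch(day_kind,
    habituation = rep(90, n_blocks - 1L),
    recall      = rep(90, n_blocks - 1L),
    training    = with_seed(seed, runif(n_blocks - 1L, 60, 120))
  )
  starts <- lead_in + c(0, cumsum(gaps + block_len))
  ends <- starts + block_len
  beeps <- as.vector(vapply(starts, function(s) s + 0:29, numeric(30)))
  us_onsets <- if (day_kind == "training") ends else numeric(0)
  us_duration <- if (day_kind == "training") 1 else 0
  session_length <- ends[n_blocks] + us_duration + lead_out

  structure(list(
    day_kind = day_kind,
    beep_onsets = beeps,
    block_intervals = data.frame(start = starts, end = ends),
    us_onsets = us_onsets,
    us_duration = us_duration,
    session_length = session_length
  ), class = "ExperimentSchedule")
}

#' @export
print.ExperimentSchedule <- function(x, ...) {
  cat(sprintf(
    "<ExperimentSchedule> %s: %d CS blocks (%d beeps), %d US, %.0f s\n",
    x$day_kind, nrow(x$block_intervals), length(x$beep_onsets),
    length(x$us_onsets), x$session_length
  ))
  invisible(x)
}

validate_schedule <- function(schedule) {
  if (!inherits(schedule, "ExperimentSchedule")) {
    stop_invalid("expected an ExperimentSchedule")
  }
  invisible(schedule)
}
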