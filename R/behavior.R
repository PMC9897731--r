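#' Segment freezing bouts from a movement index
#'
#' A frame is freezing iff it belongs to a maximal run of below-threshold
#' frames lasting at least `min_duration`. Default thresholds follow the
#' standard operational definitions: 40 a.u. without a cable attached to the
#' head stage, 120 a.u. with cable; minimum duration 0.5 s. A run truncated
#' by either trace end still counts if long enough.
#'
#' @param movement_index numeric vector, one value per video frame (a.u.).
#' @param frame_rate frames per second.
#' @param threshold freezing threshold, a.u.; overrides `cable`.
#' @param cable logical; selects the 120 a.u. threshold when `TRUE`.
#' @param min_duration minimum bout duration, s.
#' @return integer vector, 1 = freezing, 0 = moving.
#' @export
detect_freezing <- function(movement_index, frame_rate = 30, threshold = NULL,
                            cable = FALSE, min_duration = 0.5) {
  if (length(movement_index) == 0L) stop_invalid("empty movement index")
  if (is.null(threshold)) threshold <- if (cable) 120 else 40
  check_number(threshold, "threshold", 1e-12)
  check_number(min_duration, "min_duration", 0)
  check_number(frame_rate, "frame_rate", 1e-9)

  below <- movement_index < threshold
  r <- rle(below)
  min_frames <- ceiling(min_duration * frame_rate - 1e-9)
  keep <- r$values & r$lengths >= min_frames
  as.integer(inverse.rle(list(lengths = r$lengths, values = keep)))
}

#' Binned percent time freezing
#'
#' @param freezing binary freezing trace (per frame).
#' @param frame_rate frames per second.
#' @param bin_width bin width, s (default 10 s); must span a whole number of
#'   frames. A trailing partial bin is dropped.
#' @return data.frame with `bin_start` (s) and `percent` (0-100).
#' @export
percent_freezing <- function(freezing, frame_rate = 30, bin_width = 10) {
  check_number(bin_width, "bin_width", 1e-9)
  frames_per_bin <- bin_width * frame_rate
  if (frames_per_bin < 1) stop_invalid("bin shorter than one frame")
  if (abs(frames_per_bin - round(frames_per_bin)) > 1e-9) {
    stop_invalid("bin_width must span a whole number of frames")
  }
  frames_per_bin <- as.integer(round(frames_per_bin))
  n_bins <- length(freezing) %/% frames_per_bin
  if (n_bins == 0L) {
    return(data.frame(bin_start = numeric(0), percent = numeric(0)))
  }
  m <- matrix(freezing[seq_len(n_bins * frames_per_bin)], nrow = frames_per_bin)
  data.frame(
    bin_start = (seq_len(n_bins) - 1) * bin_width,
    percent = 100 * colMeans(m)
  )
}

#' Movement-ON events (freezing-to-moving transitions)
#'
#' @param freezing binary freezing trace.
#' @param frame_rate frames per second.
#' @return numeric vector of event times (s): the time of the first moving
#'   frame of each transition, on a clock where frame 1 is t = 0.
#' @export
movement_on_events <- function(freezing, frame_rate = 30) {
  if (length(freezing) < 2L) return(numeric(0))
  idx <- which(diff(freezing) == -1L) + 1L
  (idx - 1) / frame_rate
}

#' Label CS and no-CS analysis epochs of a session
#'
#' CS epochs are the schedule's 30 s tone blocks. No-CS epochs are windows of
#' the same length placed, by default, centered midway between consecutive
#' blocks plus one centered 45 s after the last block; any window that would
#' fall within 5 s after a footshock or overlap a CS block raises an error.
#'
#' @param schedule an [build_schedule()] result.
#' @param no_cs_offset center of the trailing no-CS window relative to the
#'   last block end, s.
#' @param us_guard quiet time required after each US, s.
#' @return data.frame with `start`, `end` (s) and `label` (`"CS"`/`"noCS"`).
#' @export
build_epochs <- function(schedule, no_cs_offset = 45, us_guard = 5) {
  validate_schedule(schedule)
  bl <- schedule$block_intervals
  len <- bl$end[1] - bl$start[1]
  centers <- c(
    if (nrow(bl) > 1) (bl$end[-nrow(bl)] + bl$start[-1]) / 2,
    bl$end[nrow(bl)] + no_cs_offset
  )
  no_cs <- data.frame(start = centers - len / 2, end = centers + len / 2,
                      label = "noCS")
  cs <- data.frame(start = bl$start, end = bl$end, label = "CS")
  for (i in seq_len(nrow(no_cs))) {
    if (any(no_cs$start[i] < cs$end & no_cs$end[i] > cs$start)) {
      stop_invalid("no-CS window overlaps a CS block")
    }
    if (length(schedule$us_onsets) &&
        any(no_cs$start[i] < schedule$us_onsets + schedule$us_duration + us_guard &
            no_cs$end[i] > schedule$us_onsets)) {
      stop_invalid("no-CS window overlaps the post-footshock guard period")
    }
    if (no_cs$end[i] > schedule$session_length) {
      stop_invalid("no-CS window extends past the session end")
    }
  }
  out <- rbind(cs, no_cs)
  out[order(out$start), , drop = FALSE]
}
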