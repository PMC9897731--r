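#' Event-triggered average of Z-scored traces
#'
#' Averages peri-event snippets of each neuron's Z-scored trace at the
#' calcium sampling rate. The sample taken as the event onset is the nearest
#' sample to the event time; events whose window would extend past either
#' trace edge are dropped and counted.
#'
#' @param zmat neurons x time matrix of Z-scored traces.
#' @param rate sampling rate, Hz.
#' @param event_times event onset times, s (frame 1 is t = 0).
#' @param window c(lo, hi) window in s relative to onset; samples at offsets
#'   `k/rate` with `lo <= k/rate < hi` are stored.
#' @param ids optional neuron ids (defaults to row indices).
#' @return list of class `AlignedResponse`: `mean_z` neurons x offsets
#'   matrix, `offsets` (s), `n_events` used, `n_dropped`, `ids`.
#' @export
align_events <- function(zmat, rate, event_times, window = c(-2, 4),
                         ids = seq_len(nrow(zmat))) {
  if (!is.matrix(zmat)) zmat <- matrix(zmat, nrow = 1)
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2]) {
    stop_invalid("window must be finite c(lo, hi) with lo < hi")
  }
  ks <- seq(ceiling(window[1] * rate - 1e-9), floor(window[2] * rate - 1 + 1e-9))
  n_t <- ncol(zmat)
  onset <- round(event_times * rate) + 1L
  ok <- onset + ks[1] >= 1L & onset + ks[length(ks)] <= n_t
  n_dropped <- sum(!ok)
  onset <- onset[ok]
  if (length(onset) == 0L) {
    stop_degenerate("no usable events within the trace span")
  }
  acc <- matrix(0, nrow(zmat), length(ks))
  for (o in onset) acc <- acc + zmat[, o + ks, drop = FALSE]
  structure(list(
    mean_z = acc / length(onset), offsets = ks / rate,
    n_events = length(onset), n_dropped = n_dropped, ids = ids
  ), class = "AlignedResponse")
}

#' Mean Z over a classification sub-window
#'
#' @param aligned an [align_events()] result.
#' @param window c(lo, hi) in s; half-open \[lo, hi).
#' @return named numeric vector of per-neuron mean Z.
#' @export
mean_window_z <- function(aligned, window) {
  stopifnot(inherits(aligned, "AlignedResponse"))
  sel <- aligned$offsets >= window[1] - 1e-9 & aligned$offsets < window[2] - 1e-9
  if (!any(sel)) stop_invalid("classification window contains no samples")
  stats::setNames(rowMeans(aligned$mean_z[, sel, drop = FALSE]), aligned$ids)
}

#' Classification windows and thresholds per event kind
#'
#' Footshock (US) responses are called on the mean Z over \[0, 1\] s with
#' threshold 1.0; tone-beep (CS) and movement-ON responses on \[0, 0.5\] s
#' with threshold 0.2.
#'
#' @param kind one of `"US"`, `"CS_beep"`, `"movON_CS"`, `"movON_noCS"`.
#' @return list with `window` (s) and `threshold`.
#' @export
responder_criteria <- function(kind) {
  switch(kind,
    US = list(window = c(0, 1), threshold = 1.0),
    CS_beep = ,
    movON_CS = ,
    movON_noCS = list(window = c(0, 0.5), threshold = 0.2),
    stop_invalid("unknown event kind: ", kind)
  )
}

#' Call responders from aligned responses
#'
#' @param aligned_by_kind named list of [align_events()] results; names are
#'   event kinds understood by [responder_criteria()].
#' @param day session label stored alongside the flags.
#' @param criteria optional overrides: named list of `list(window, threshold)`.
#' @return `ResponderTable` data.frame: `neuron`, `day`, `kind`,
#'   `mean_window_z`, `n_events`, `responder`.
#' @export
classify_responders <- function(aligned_by_kind, day = NA_character_,
                                criteria = NULL) {
  if (length(aligned_by_kind) == 0L) stop_invalid("no aligned responses given")
  rows <- lapply(names(aligned_by_kind), function(kind) {
    crit <- if (!is.null(criteria[[kind]])) criteria[[kind]] else responder_criteria(kind)
    al <- aligned_by_kind[[kind]]
    z <- mean_window_z(al, crit$window)
    data.frame(
      neuron = al$ids, day = day, kind = kind,
      mean_window_z = as.numeric(z), n_events = al$n_events,
      responder = as.numeric(z) > crit$threshold
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ResponderTable", "data.frame")
  out
}

#' Remove confound-coupled trials from CS and movement-ON analyses
#'
#' Tone beeps followed within `window` s by a movement-ON transition are
#' removed from the CS analysis (the response could reflect movement rather
#' than the tone); movement-ON transitions preceded within `window` s by a
#' beep are removed from the movement analysis.
#'
#' @param beep_times,movement_on_times sorted event times, s.
#' @param window exclusion window, s.
#' @return list with `clean_beeps`, `clean_movons`, `frac_beeps_excluded`,
#'   `frac_movons_excluded`.
#' @export
exclude_confounded <- function(beep_times, movement_on_times, window = 0.5) {
  check_number(window, "window", 0)
  bad_beep <- vapply(beep_times, function(b) {
    any(movement_on_times >= b & movement_on_times <= b + window)
  }, logical(1))
  bad_mov <- vapply(movement_on_times, function(m) {
    any(beep_times >= m - window & beep_times <= m)
  }, logical(1))
  list(
    clean_beeps = beep_times[!bad_beep],
    clean_movons = movement_on_times[!bad_mov],
    frac_beeps_excluded = if (length(beep_times)) mean(bad_beep) else 0,
    frac_movons_excluded = if (length(movement_on_times)) mean(bad_mov) else 0
  )
}

#' Remove duplicate cells imaged on two focal planes
#'
#' Cells detected on different focal planes whose centers lie within
#' `dist_thresh` um laterally and whose Z-scored traces correlate above
#' `cor_thresh` are considered the same neuron seen twice; the dimmer member
#' (lower mean raw fluorescence, i.e. more out of focus) is dropped.
#' Removal iterates until no violating pair remains.
#'
#' @param traceset a `TraceSet`.
#' @param dist_thresh lateral distance gate, um.
#' @param cor_thresh Pearson correlation gate on Z-scored traces.
#' @return list with `traceset` (deduplicated) and `removed` (ids).
#' @export
remove_duplicates <- function(traceset, dist_thresh = 20, cor_thresh = 0.7) {
  stopifnot(inherits(traceset, "TraceSet"))
  n <- nrow(traceset$traces)
  if (n < 2L) return(list(traceset = traceset, removed = traceset$ids[0]))

  zmat <- t(apply(traceset$traces, 1, zscore_trace))
  intensity <- rowMeans(traceset$traces)
  d <- as.matrix(dist(traceset$coords))
  cross <- outer(traceset$plane, traceset$plane, "!=")
  cand <- which(upper.tri(d) & d < dist_thresh & cross, arr.ind = TRUE)

  alive <- rep(TRUE, n)
  removed <- integer(0)
  repeat {
    worst <- NULL
    worst_cor <- cor_thresh
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!alive[i] || !alive[j]) next
      cc <- cor(zmat[i, ], zmat[j, ])
      if (cc > worst_cor) {
        worst <- c(i, j); worst_cor <- cc
      }
    }
    if (is.null(worst)) break
    drop <- if (intensity[worst[1]] <= intensity[worst[2]]) worst[1] else worst[2]
    alive[drop] <- FALSE
    removed <- c(removed, drop)
  }

  keep <- which(alive)
  ts <- new_traceset(
    traceset$traces[keep, , drop = FALSE],
    traceset$coords[keep, , drop = FALSE],
    traceset$plane[keep], traceset$rate, traceset$ids[keep]
  )
  list(traceset = ts, removed = traceset$ids[!alive])
}

#' Run the per-session classification pipeline
#'
#' Duplicate removal, Z-scoring, deconvolution, confound exclusion,
#' event alignment and responder classification for one session.
#'
#' @param traceset a `TraceSet` for the session.
#' @param schedule the session's [build_schedule()] result.
#' @param behavior the session's `BehaviorTrace`.
#' @param day label stored in the responder table (defaults to the
#'   schedule's `day_kind`).
#' @param exclusion_window confound window, s (see [exclude_confounded()]).
#' @param gamma,lambda deconvolution parameters (see [deconvolve_traceset()]).
#' @param dedup apply [remove_duplicates()] first.
#' @return list with `responders` (`ResponderTable`), `events` (deconvolved,
#'   sigma-normalized), `zmat`, `traceset` (post-dedup), `removed` ids,
#'   `aligned` (per kind), `exclusions`.
#' @export
analyze_session <- function(traceset, schedule, behavior,
                            day = schedule$day_kind, exclusion_window = 0.5,
                            gamma = NULL, lambda = NULL, dedup = TRUE) {
  validate_schedule(schedule)
  dd <- if (dedup) remove_duplicates(traceset) else
    list(traceset = traceset, removed = traceset$ids[0])
  ts <- dd$traceset
  zmat <- t(apply(ts$traces, 1, zscore_trace))
  events <- deconvolve_traceset(ts, gamma = gamma, lambda = lambda)

  freezing <- detect_freezing(behavior$movement_index, behavior$frame_rate)
  movons <- movement_on_events(freezing, behavior$frame_rate)
  excl <- exclude_confounded(schedule$beep_onsets, movons, exclusion_window)

  bl <- schedule$block_intervals
  mov_in_cs <- in_intervals(excl$clean_movons, bl$start, bl$end)

  aligned <- list()
  if (length(schedule$us_onsets)) {
    aligned$US <- align_events(zmat, ts$rate, schedule$us_onsets, ids = ts$ids)
  }
  if (length(excl$clean_beeps)) {
    aligned$CS_beep <- align_events(zmat, ts$rate, excl$clean_beeps, ids = ts$ids)
  }
  if (any(mov_in_cs)) {
    aligned$movON_CS <- align_events(zmat, ts$rate, excl$clean_movons[mov_in_cs],
                                     ids = ts$ids)
  }
  if (any(!mov_in_cs)) {
    aligned$movON_noCS <- align_events(zmat, ts$rate, excl$clean_movons[!mov_in_cs],
                                       ids = ts$ids)
  }
  responders <- classify_responders(aligned, day = day)
  list(responders = responders, events = events, zmat = zmat, traceset = ts,
       removed = dd$removed, aligned = aligned, exclusions = excl)
}
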