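#' Write / read a TraceSet as CSV + JSON sidecar
#'
#' `traces.csv` holds one row per neuron (id followed by samples),
#' `cells.csv` the coordinates and plane ids, `traceset.json` the sampling
#' rate. Round trips are exact up to float printing (15 significant digits).
#'
#' @param traceset a `TraceSet`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_traceset <- function(traceset, dir) {
  stopifnot(inherits(traceset, "TraceSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- data.table::data.table(neuron = traceset$ids, traceset$traces)
  data.table::fwrite(tr, file.path(dir, "traces.csv"))
  cells <- data.table::data.table(
    neuron = traceset$ids, x_um = traceset$coords[, 1],
    y_um = traceset$coords[, 2], plane = traceset$plane
  )
  data.table::fwrite(cells, file.path(dir, "cells.csv"))
  jsonlite::write_json(list(rate_hz = traceset$rate,
                            n_neurons = nrow(traceset$traces),
                            n_samples = ncol(traceset$traces)),
                       file.path(dir, "traceset.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_traceset
#' @export
read_traceset <- function(dir) {
  for (f in c("traces.csv", "cells.csv", "traceset.json")) {
    if (!file.exists(file.path(dir, f))) {
      stop_invalid("not a TraceSet directory (missing ", f, "): ", dir)
    }
  }
  meta <- jsonlite::read_json(file.path(dir, "traceset.json"))
  tr <- data.table::fread(file.path(dir, "traces.csv"))
  cells <- data.table::fread(file.path(dir, "cells.csv"))
  if (nrow(tr) != nrow(cells)) {
    stop_invalid("traces.csv and cells.csv disagree on the number of neurons")
  }
  m <- as.matrix(tr[, -1])
  dimnames(m) <- NULL
  new_traceset(m, cbind(x = cells$x_um, y = cells$y_um), cells$plane,
               meta$rate_hz, ids = tr[[1]])
}

#' Write / read an event table (deconvolved calcium events) as CSV
#'
#' Columns `neuron`, `time_s`, `amplitude_sigma`. An empty file with a
#' header is a valid empty event series.
#'
#' @param events data.frame `neuron`, `time`, `amplitude`.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(
    data.table::data.table(neuron = events$neuron, time_s = events$time,
                           amplitude_sigma = events$amplitude),
    path
  )
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  dt <- data.table::fread(path)
  need <- c("neuron", "time_s", "amplitude_sigma")
  if (!all(need %in% names(dt))) {
    stop_invalid("malformed events file (need columns ",
                 paste(need, collapse = ", "), "): ", path)
  }
  data.frame(neuron = dt$neuron, time = dt$time_s, amplitude = dt$amplitude_sigma)
}

#' Write / read a behavior trace as per-frame CSV
#'
#' Columns `time_s`, `movement_index`, `freezing`.
#'
#' @param behavior a `BehaviorTrace`; `freezing` is computed with
#'   [detect_freezing()] defaults unless supplied.
#' @param path CSV path.
#' @param freezing optional precomputed binary trace.
#' @export
write_behavior <- function(behavior, path, freezing = NULL) {
  if (is.null(freezing)) {
    freezing <- detect_freezing(behavior$movement_index, behavior$frame_rate)
  }
  data.table::fwrite(
    data.table::data.table(time_s = behavior$time,
                           movement_index = behavior$movement_index,
                           freezing = freezing),
    path
  )
  invisible(path)
}

#' @rdname write_behavior
#' @param frame_rate frames per second of the stored trace.
#' @export
read_behavior <- function(path, frame_rate = 30) {
  dt <- data.table::fread(path)
  need <- c("time_s", "movement_index", "freezing")
  if (!all(need %in% names(dt))) {
    stop_invalid("malformed behavior file (need columns ",
                 paste(need, collapse = ", "), "): ", path)
  }
  structure(list(movement_index = dt$movement_index,
                 state = as.integer(dt$freezing == 0L),
                 frame_rate = frame_rate, time = dt$time_s),
            class = "BehaviorTrace")
}

#' Write a schedule as an event CSV (one row per timed event)
#'
#' @param schedule an `ExperimentSchedule`.
#' @param path CSV path.
#' @export
write_schedule <- function(schedule, path) {
  validate_schedule(schedule)
  bl <- schedule$block_intervals
  rows <- rbind(
    data.frame(event = "beep", time_s = schedule$beep_onsets, end_s = NA_real_),
    data.frame(event = "cs_block", time_s = bl$start, end_s = bl$end),
    if (length(schedule$us_onsets)) {
      data.frame(event = "us", time_s = schedule$us_onsets,
                 end_s = schedule$us_onsets + schedule$us_duration)
    }
  )
  rows <- rows[order(rows$time_s, rows$event), ]
  attrline <- data.frame(event = "session", time_s = 0,
                         end_s = schedule$session_length)
  data.table::fwrite(rbind(attrline, rows), path)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' The configuration must carry a `seed`; every analysis threshold has a
#' package default and may be overridden under `params`.
#'
#' @param path JSON file.
#' @return list of class `RunConfig`.
#' @export
read_run_config <- function(path) {
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_invalid("cannot parse config: ",
                                                   conditionMessage(e)))
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a plain list (e.g. already-parsed JSON).
#' @export
as_run_config <- function(cfg) {
  if (is.null(cfg$seed)) stop_invalid("config error: `seed` is mandatory")
  defaults <- list(
    days = c("habituation", "training", "recall"),
    stages = c("simulate", "deconvolve", "behavior", "classify", "state",
               "population", "stats"),
    behavior = list(),   # behavior_spec() overrides
    population = list(), # population_spec() overrides
    freezing_threshold = 40,
    freezing_min_duration = 0.5,
    exclusion_window = 0.5,
    dedup = TRUE,
    exclude_us_state = TRUE
  )
  out <- utils::modifyList(defaults, cfg[!vapply(cfg, is.null, TRUE)])
  out$seed <- as.integer(out$seed)
  class(out) <- "RunConfig"
  out
}
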