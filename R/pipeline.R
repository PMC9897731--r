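#' Run the full synthetic pipeline end to end
#'
#' Executes, per configured day, the stages
#' simulate -> deconvolve -> behavior -> classify -> state, then the
#' cross-day population and statistics stages, writing every stage output as
#' CSV/JSON under `out_dir` together with a manifest (config hash, seed,
#' package version, completed stages). Reruns with the same configuration
#' reproduce the outputs byte-identically.
#'
#' @param config a `RunConfig` (see [read_run_config()] / [as_run_config()]),
#'   or a plain list with at least `seed`.
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "RunConfig")) config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  need <- function(stage, dep) {
    if (!dep %in% stages) {
      stop_dependency("stage '", stage, "' requires stage '", dep,
                      "' which is toggled off")
    }
  }
  responder_tables <- list()
  completed <- character(0)
  day_seed <- function(day, off) config$seed + 1000L * match(day, config$days) + off

  for (day in config$days) {
    ddir <- file.path(out_dir, day)
    dir.create(ddir, showWarnings = FALSE)
    if (!"simulate" %in% stages) stop_dependency("nothing to do: stage 'simulate' is off")
    schedule <- build_schedule(day, seed = day_seed(day, 1L))
    bspec <- do.call(behavior_spec, utils::modifyList(
      list(seed = day_seed(day, 2L)), config$behavior))
    behavior <- simulate_behavior(schedule, bspec)
    pspec <- do.call(population_spec, utils::modifyList(
      list(seed = day_seed(day, 3L)), config$population))
    sim <- simulate_population(schedule, behavior, pspec)
    write_schedule(schedule, file.path(ddir, "schedule.csv"))
    write_traceset(sim$traceset, file.path(ddir, "traceset"))

    if ("behavior" %in% stages) {
      freezing <- detect_freezing(behavior$movement_index, behavior$frame_rate,
                                  threshold = config$freezing_threshold,
                                  min_duration = config$freezing_min_duration)
      write_behavior(behavior, file.path(ddir, "behavior.csv"), freezing)
      data.table::fwrite(percent_freezing(freezing, behavior$frame_rate),
                         file.path(ddir, "percent_freezing.csv"))
    }

    if ("classify" %in% stages) {
      need("classify", "deconvolve")
      need("classify", "behavior")
      res <- analyze_session(sim$traceset, schedule, behavior, day = day,
                             exclusion_window = config$exclusion_window,
                             dedup = config$dedup)
      write_events(res$events, file.path(ddir, "events.csv"))
      data.table::fwrite(res$responders, file.path(ddir, "responders.csv"))
      jsonlite::write_json(
        list(removed_duplicates = res$removed,
             frac_beeps_excluded = res$exclusions$frac_beeps_excluded,
             frac_movons_excluded = res$exclusions$frac_movons_excluded),
        file.path(ddir, "exclusions.json"), auto_unbox = TRUE, digits = NA)
      responder_tables[[day]] <- res$responders

      if ("state" %in% stages) {
        st <- label_state_intervals(freezing, behavior$frame_rate, schedule,
                                    exclude_us = config$exclude_us_state)
        act <- amplitude_weighted_frequency(res$events, st,
                                            neurons = res$traceset$ids, day = day)
        data.table::fwrite(act, file.path(ddir, "state_activity.csv"))
      }
    }
  }

  if ("population" %in% stages && length(responder_tables)) {
    need("population", "classify")
    all_resp <- do.call(rbind, responder_tables)
    data.table::fwrite(fractions_by_day(all_resp),
                       file.path(out_dir, "fractions_by_day.csv"))
    if ("training" %in% names(responder_tables)) {
      ov <- overlap_counts(responder_tables$training, "training")
      jsonlite::write_json(list(day = ov$day, total = ov$total,
                                counts = as.list(ov$counts)),
                           file.path(out_dir, "overlap_training.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if ("stats" %in% stages && length(responder_tables)) {
    need("stats", "classify")
    all_resp <- do.call(rbind, responder_tables)
    fr <- fractions_by_day(all_resp)
    cs <- fr[fr$kind == "CS_beep", , drop = FALSE]
    stats_out <- list()
    if (nrow(cs) >= 2) {
      tab <- rbind(cs$n_responders, cs$n_total - cs$n_responders)
      ct <- chi_square_independence(tab)
      stats_out$cs_fraction_chisq <- list(statistic = ct$statistic, df = ct$df,
                                          p = ct$p)
    }
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  completed <- intersect(
    c("simulate", "deconvolve", "behavior", "classify", "state", "population",
      "stats"), stages)
  cfg_plain <- unclass(config)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    package = "vtsfear",
    version = as.character(utils::packageVersion("vtsfear")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages_completed = completed
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
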