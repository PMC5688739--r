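#' Preset run configurations
#'
#' Three bundled experiment presets mirror the monitor's validation and
#' application studies, so each can be reproduced with one call:
#'
#' * `"clock-validation"`: a 30-min analog-clock recording (1 s ticks,
#'   5 ms timestamp jitter, 2% missed ticks) for interval statistics, plus
#'   a modulated variant (10 ms sinusoidal interval modulation at the 60 s
#'   second-hand rotation period) for rhythm detection.
#' * `"crosstalk-shield"`: three neighboring cages recorded for 30 min;
#'   only cage 2 is occupied (homogeneous 0.5 events/s), its events are
#'   picked up by the unshielded cage-1 channel with probability 0.26,
#'   and an aluminum sheet shields the cage-2/cage-3 pair.
#' * `"circadian-shift"`: 6 days of two-strain activity (4 control CD1-like
#'   and 3 hyperactive LAB-like animals) under an inverted 12 h/12 h cycle
#'   (lights ON 8 PM, OFF 8 AM) advanced by 6 h at day 3 by shortening
#'   that day's dark period; each animal is passed through the logger
#'   model and binned at 1 h.
#'
#' @param preset preset name.
#' @param seed integer master seed; per-animal seeds are derived from it.
#' @return a named config list (class `cagewatch_config`) accepted by
#'   [run_pipeline()]. The list serializes losslessly through
#'   [write_config()]/[read_config()].
#' @export
preset_config <- function(preset = c("clock-validation", "crosstalk-shield",
                                     "circadian-shift"), seed = 1) {
  preset <- match.arg(preset)
  cfg <- switch(
    preset,
    "clock-validation" = list(
      preset = preset, seed = seed,
      duration_s = 1800, tick_interval = 1,
      jitter_sd = 0.005, miss_prob = 0.02,
      mod_period = 60, mod_amplitude = 0.010,
      range_lo = 0.95, range_hi = 1.05,
      percentiles = c(1, 5, 25, 50, 75, 95, 99)
    ),
    "crosstalk-shield" = list(
      preset = preset, seed = seed,
      duration_s = 1800, rate = 0.5, occupied = 2,
      pickup = 0.26, neighbor = 1, shield = c(2, 3),
      dead_time = 0.1, hold = 1
    ),
    "circadian-shift" = list(
      preset = preset, seed = seed,
      days = 6, n_cd1 = 4, n_lab = 3,
      light_on = "20:00", light_off = "08:00",
      shift_day = 3, shift_at = "08:00", shift_h = -6,
      bin_width_s = 3600, modulation_window_h = 3,
      baseline_days = c(1, 2), post_days = c(5, 6), exclude_day = 3,
      dead_time = 0.1, hold = 1
    )
  )
  structure(cfg, class = c("cagewatch_config", "list"))
}

#' Serialize / restore a run configuration
#'
#' @param config a config list from [preset_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   restored config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  num <- c("shift_day", "shift_h", "baseline_days", "post_days",
           "percentiles", "shield", "exclude_day")
  for (k in intersect(num, names(cfg))) cfg[[k]] <- as.numeric(cfg[[k]])
  structure(cfg, class = c("cagewatch_config", "list"))
}

#' The light protocol of the circadian preset
#'
#' @param config a `"circadian-shift"` config (default preset values).
#' @return a [light_schedule()].
#' @export
circadian_schedule <- function(config = preset_config("circadian-shift")) {
  light_schedule(
    config$light_on, config$light_off,
    shifts = schedule_shift(config$shift_day, config$shift_at, config$shift_h)
  )
}

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max %/% 2, n)
}

#' Execute a configured pipeline run
#'
#' Runs simulate -> log -> analyze for the configured experiment and,
#' when `out_dir` is given, writes its artifact bundle: CSV logs and
#' result tables, a JSON summary, and a `manifest.json` recording the
#' configuration, seed and config hash, which suffices to reproduce the
#' bundle. Outputs are byte-identical for identical config and seed.
#'
#' @param config config list from [preset_config()] or [read_config()].
#' @param out_dir optional output directory (created if missing).
#' @return a results list, invisibly when writing, whose elements depend
#'   on the preset (see [preset_config()]).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.null(config$preset)) abort("Config has no `preset` entry.")
  res <- switch(
    config$preset,
    "clock-validation" = run_clock_validation(config),
    "crosstalk-shield" = run_crosstalk_shield(config),
    "circadian-shift" = run_circadian_shift(config),
    abort(paste0("Unknown preset '", config$preset, "'."))
  )
  if (!is.null(out_dir)) {
    write_bundle(res, config, out_dir)
  }
  res
}

#' @rdname run_pipeline
#' @param preset preset name, passed to [preset_config()].
#' @param seed integer master seed.
#' @export
run_preset <- function(preset, seed = 1, out_dir = NULL) {
  run_pipeline(preset_config(preset, seed), out_dir)
}

run_clock_validation <- function(cfg) {
  seeds <- derive_seeds(cfg$seed, 2)
  base <- simulate_clock(cfg$duration_s, cfg$tick_interval,
                         jitter_sd = cfg$jitter_sd, miss_prob = cfg$miss_prob,
                         seed = seeds[1])
  iv <- event_intervals(base)
  summ <- interval_summary(iv, cfg$percentiles)
  modulated <- simulate_clock(cfg$duration_s, cfg$tick_interval,
                              jitter_sd = cfg$jitter_sd, miss_prob = 0,
                              mod_period = cfg$mod_period,
                              mod_amplitude = cfg$mod_amplitude,
                              seed = seeds[2])
  rhythm <- dominant_period(event_intervals(modulated))
  list(
    preset = cfg$preset,
    trace = base,
    summary = summ,
    fraction_in_range = fraction_in_range(iv, cfg$range_lo, cfg$range_hi),
    histogram = interval_histogram(iv),
    rhythm = rhythm
  )
}

run_crosstalk_shield <- function(cfg) {
  seeds <- derive_seeds(cfg$seed, 2)
  prof <- strain_profile("homogeneous", rate_active = cfg$rate,
                         rate_rest = cfg$rate, entrainment_rate = 0)
  trace <- simulate_mouse(prof, light_schedule(), seed = seeds[1],
                          duration_s = cfg$duration_s)
  xt <- diag(6)
  xt[cfg$occupied, cfg$neighbor] <- cfg$pickup
  xt[cfg$occupied, cfg$shield[cfg$shield != cfg$occupied][1]] <- cfg$pickup
  cages <- cage_array(setNames(list(trace), cfg$occupied), crosstalk = xt,
                      shields = list(cfg$shield))
  log <- log_events(cages, seed = seeds[2], dead_time = cfg$dead_time,
                    hold = cfg$hold)
  counts <- colSums(as.matrix(log[paste0("ch", 1:6)]))
  shielded_ch <- cfg$shield[cfg$shield != cfg$occupied][1]
  list(
    preset = cfg$preset,
    log = log,
    channel_counts = tibble(channel = 1:6, count = as.integer(counts)),
    pickup_pct = 100 * counts[[cfg$neighbor]] / counts[[cfg$occupied]],
    shielded_count = as.integer(counts[[shielded_ch]])
  )
}

run_circadian_shift <- function(cfg) {
  sch <- circadian_schedule(cfg)
  n <- cfg$n_cd1 + cfg$n_lab
  seeds <- derive_seeds(cfg$seed, 2 * n)
  profiles <- c(replicate(cfg$n_cd1, cd1_profile(), simplify = FALSE),
                replicate(cfg$n_lab, lab_profile(), simplify = FALSE))
  ids <- c(paste0("CD1-", seq_len(cfg$n_cd1)),
           paste0("LAB-", seq_len(cfg$n_lab)))
  binned <- vector("list", n)
  logs <- vector("list", n)
  mods <- vector("list", n)
  for (k in seq_len(n)) {
    tr <- simulate_mouse(profiles[[k]], sch, days = cfg$days,
                         seed = seeds[k], animal_id = ids[k])
    cages <- cage_array(list("1" = tr))
    log <- log_events(cages, seed = seeds[n + k], dead_time = cfg$dead_time,
                      hold = cfg$hold, schedule = sch)
    logs[[k]] <- log
    binned[[k]] <- bin_activity(log, channel = 1,
                                bin_width_s = cfg$bin_width_s,
                                days = cfg$days, animal_id = ids[k])
    mods[[k]] <- light_modulation(log, sch, window_h = cfg$modulation_window_h,
                                  channel = 1,
                                  span_s = c(0, cfg$days * 86400)) %>%
      mutate(animal_id = ids[k])
  }
  names(logs) <- names(binned) <- ids
  strain <- rep(c("CD1", "LAB"), c(cfg$n_cd1, cfg$n_lab))
  all_binned <- bind_rows(binned)
  shift <- lapply(split(seq_len(n), strain), function(ix) {
    grp <- bind_rows(binned[ix])
    estimate_phase_shift(
      daily_profile(grp %>% filter(.data$day %in% cfg$baseline_days)),
      daily_profile(grp %>% filter(.data$day %in% cfg$post_days))
    )
  })
  list(
    preset = cfg$preset,
    schedule = sch,
    logs = logs,
    binned = all_binned,
    strain = tibble(animal_id = ids, strain = strain),
    actogram_cd1 = group_actogram(binned[strain == "CD1"]),
    actogram_lab = group_actogram(binned[strain == "LAB"]),
    daily = daily_totals(all_binned),
    modulation = bind_rows(mods),
    phase_shift = bind_rows(shift, .id = "strain")
  )
}

write_bundle <- function(res, cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "cagewatch",
    version = as.character(utils::packageVersion("cagewatch")),
    preset = cfg$preset, seed = cfg$seed,
    config = unclass(cfg), config_hash = rlang::hash(unclass(cfg))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (cfg$preset == "clock-validation") {
    readr::write_csv(res$trace, file.path(out_dir, "clock_trace.csv"),
                     progress = FALSE)
    readr::write_csv(res$histogram, file.path(out_dir, "interval_histogram.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(n_events = res$summary$n_events, mean = res$summary$mean,
           median = res$summary$median,
           percentiles = as.list(res$summary$percentiles),
           fraction_in_range = res$fraction_in_range,
           dominant_period_s = res$rhythm$period_s,
           rhythmic = res$rhythm$rhythmic),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  } else if (cfg$preset == "crosstalk-shield") {
    write_event_log(res$log, file.path(out_dir, "crosstalk_log.csv"))
    jsonlite::write_json(
      list(pickup_pct = res$pickup_pct, shielded_count = res$shielded_count,
           channel_counts = res$channel_counts),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  } else if (cfg$preset == "circadian-shift") {
    for (id in names(res$logs)) {
      write_event_log(res$logs[[id]],
                      file.path(out_dir, paste0("log_", id, ".csv")))
    }
    readr::write_csv(res$binned, file.path(out_dir, "binned_activity.csv"),
                     progress = FALSE)
    readr::write_csv(res$actogram_cd1, file.path(out_dir, "actogram_cd1.csv"),
                     progress = FALSE)
    readr::write_csv(res$actogram_lab, file.path(out_dir, "actogram_lab.csv"),
                     progress = FALSE)
    readr::write_csv(res$modulation, file.path(out_dir, "modulation.csv"),
                     progress = FALSE)
    readr::write_csv(res$daily, file.path(out_dir, "daily_totals.csv"),
                     progress = FALSE)
    readr::write_csv(res$phase_shift, file.path(out_dir, "phase_shift.csv"),
                     progress = FALSE)
  }
  invisible(out_dir)
}
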