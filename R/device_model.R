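#' Retriggerable pulse extension
#'
#' Models the monostable multivibrators on the detector interface board,
#' which stretch microsecond Doppler pulses to pulses of at least `hold`
#' seconds: every event restarts the hold, so the output high intervals are
#' the union of `[t, t + hold)` over all events.
#'
#' @param event_times sorted (non-decreasing) event times in seconds.
#' @param hold hold time in seconds (default 1).
#' @return tibble with columns `high_start`, `high_end`: disjoint, sorted
#'   intervals during which the channel output is high.
#' @examples
#' extend_pulses(c(0, 0.4, 0.9)) # one merged 1.9 s pulse
#' @export
extend_pulses <- function(event_times, hold = 1) {
  if (hold <= 0) abort("`hold` must be positive.")
  if (is.unsorted(event_times)) abort("`event_times` must be sorted.")
  if (!length(event_times)) {
    return(tibble(high_start = numeric(), high_end = numeric()))
  }
  # with a fixed hold the running pulse end is always prev_time + hold, so a
  # new interval starts exactly when the gap to the previous event is >= hold
  grp <- cumsum(c(TRUE, diff(event_times) >= hold))
  tibble(t = event_times, grp = grp) %>%
    group_by(.data$grp) %>%
    summarise(high_start = min(.data$t), high_end = max(.data$t) + hold,
              .groups = "drop") %>%
    dplyr::select("high_start", "high_end")
}

#' Describe an array of up to six monitored cages
#'
#' @param occupancy named list mapping channel index (`"1"`..`"6"`, or
#'   unnamed positional) to an activity trace (tibble with `time_s`, or a
#'   numeric time vector); `NULL` entries are empty cages.
#' @param crosstalk 6x6 matrix; entry `[i, j]` is the probability that a
#'   physical event in cage `i` is also picked up by the detector of cage
#'   `j`. Diagonal must be 1; entries in `[0, 1]`.
#' @param shields optional list of length-2 integer vectors; each pair of
#'   neighboring cages separated by a grounded-free aluminum sheet has its
#'   mutual pickup forced to 0 (shielding eliminates crosstalk completely).
#' @return object of class `cage_array`.
#' @export
cage_array <- function(occupancy, crosstalk = diag(6), shields = NULL) {
  occ <- vector("list", 6)
  idx <- if (is.null(names(occupancy))) seq_along(occupancy)
         else as.integer(names(occupancy))
  if (any(is.na(idx)) || any(idx < 1 | idx > 6)) {
    abort("Occupancy channels must be integers 1..6.")
  }
  for (k in seq_along(occupancy)) {
    tr <- occupancy[[k]]
    if (is.null(tr)) next
    t <- if (is.data.frame(tr)) tr$time_s else as.numeric(tr)
    occ[[idx[k]]] <- sort(t)
  }
  crosstalk <- as.matrix(crosstalk)
  if (!all(dim(crosstalk) == c(6, 6)) || any(crosstalk < 0 | crosstalk > 1) ||
      any(diag(crosstalk) != 1)) {
    abort("`crosstalk` must be 6x6 in [0,1] with unit diagonal.")
  }
  for (p in shields) {
    stopifnot(length(p) == 2)
    crosstalk[p[1], p[2]] <- 0
    crosstalk[p[2], p[1]] <- 0
  }
  structure(list(occupancy = occ, crosstalk = crosstalk,
                 shields = shields %||% list()),
            class = "cage_array")
}

#' Run the logger model over a cage array
#'
#' Emulates the interrupt-driven firmware cycle. Each physical event is
#' copied to every other channel independently with the corresponding
#' crosstalk probability (0 across shielded pairs). The merged stream is
#' then processed sequentially: an event arriving at least `dead_time`
#' seconds after the previous written record raises an interrupt and a
#' record is written; its channel flags are all channels whose monostable
#' is high at that instant, i.e. channels with an event within the last
#' `hold` seconds *and* after the previous record (the monostables are
#' reset after every write). Timestamps are truncated (floored) to whole
#' seconds, matching the real-time clock's resolution.
#'
#' @param cages a [cage_array()] with at least one occupied cage.
#' @param seed integer seed for the crosstalk draws.
#' @param dead_time logger dead time in seconds (default 0.1): model
#'   parameter standing in for the SD-card write duration, during which
#'   interrupts are ignored.
#' @param hold monostable hold time in seconds (default 1).
#' @param schedule optional [light_schedule()]; when given, each record's
#'   `light` column is filled from the ambient-light state using
#'   `light_levels`, otherwise 0.
#' @param origin POSIXct midnight anchoring `time_s = 0` (default
#'   2024-01-01 00:00:00 UTC).
#' @param light_levels named integer vector `c(dark = ..., light = ...)`
#'   of 10-bit ADC readings used for the `light` column.
#' @return an event log: tibble with columns `datetime` (POSIXct, 1 s
#'   resolution, UTC), `ch1`..`ch6` (0/1 flags) and `light` (0-1023).
#' @export
log_events <- function(cages, seed, dead_time = 0.1, hold = 1,
                       schedule = NULL,
                       origin = as.POSIXct("2024-01-01 00:00:00", tz = "UTC"),
                       light_levels = c(dark = 8L, light = 840L)) {
  stopifnot(inherits(cages, "cage_array"))
  if (dead_time <= 0 || hold <= 0) abort("`dead_time` and `hold` must be > 0.")
  occupied <- which(!vapply(cages$occupancy, is.null, logical(1)))
  if (!length(occupied)) abort("All cages are empty; nothing to log.")

  set.seed(seed)
  ch_times <- vector("list", 6)
  for (i in occupied) {
    src <- cages$occupancy[[i]]
    for (j in 1:6) {
      p <- cages$crosstalk[i, j]
      if (p <= 0) next
      picked <- if (p >= 1) src else src[runif(length(src)) < p]
      ch_times[[j]] <- c(ch_times[[j]], picked)
    }
  }
  ch_times <- lapply(ch_times, function(x) if (is.null(x)) numeric() else sort(x))
  all_times <- sort(unique(unlist(ch_times)))
  if (!length(all_times)) {
    return(empty_event_log())
  }

  # sequential dead-time gating of interrupts
  rec <- logical(length(all_times))
  prev <- -Inf
  for (k in seq_along(all_times)) {
    if (all_times[k] - prev >= dead_time) {
      rec[k] <- TRUE
      prev <- all_times[k]
    }
  }
  t_rec <- all_times[rec]
  lo <- pmax(dplyr::lag(t_rec, default = -Inf), t_rec - hold)

  flags <- vapply(1:6, function(j) {
    v <- ch_times[[j]]
    if (!length(v)) return(integer(length(t_rec)))
    as.integer(findInterval(t_rec, v) - findInterval(lo, v) > 0)
  }, integer(length(t_rec)))
  flags <- matrix(flags, nrow = length(t_rec), ncol = 6,
                  dimnames = list(NULL, paste0("ch", 1:6)))

  light <- if (is.null(schedule)) {
    rep(0L, length(t_rec))
  } else {
    as.integer(light_levels[light_state(schedule, t_rec / 3600)])
  }
  out <- as_tibble(as.data.frame(flags))
  out <- dplyr::bind_cols(
    tibble(datetime = origin + floor(t_rec)), out, tibble(light = light)
  )
  out
}

empty_event_log <- function() {
  tibble(datetime = as.POSIXct(character(), tz = "UTC"),
         ch1 = integer(), ch2 = integer(), ch3 = integer(),
         ch4 = integer(), ch5 = integer(), ch6 = integer(),
         light = integer())
}

log_columns <- c("datetime", paste0("ch", 1:6), "light")

validate_event_log <- function(log) {
  if (!all(log_columns %in% names(log))) {
    abort(paste0("An event log needs columns: ",
                 paste(log_columns, collapse = ", "), "."))
  }
  flags <- as.matrix(log[paste0("ch", 1:6)])
  if (nrow(log)) {
    if (any(!flags %in% c(0L, 1L))) abort("Channel flags must be 0 or 1.")
    bad <- which(rowSums(flags) == 0)
    if (length(bad)) {
      abort(sprintf("Record %d has no channel flag set; a record is only written after an interrupt.",
                    bad[1]))
    }
    if (any(log$light < 0 | log$light > 1023)) {
      abort("`light` must be a 10-bit reading (0-1023).")
    }
  }
  invisible(log)
}

#' Write / read the comma-separated log format
#'
#' The on-disk format is the logger's native CSV: header
#' `datetime,ch1,ch2,ch3,ch4,ch5,ch6,light`, timestamps as
#' `YYYY-MM-DD HH:MM:SS` (UTC, 1 s resolution), flags 0/1, light as a
#' 10-bit integer. The round trip `read_event_log(write_event_log(x))` is
#' lossless.
#'
#' @param log an event log tibble (see [log_events()]).
#' @param path file path.
#' @return `write_event_log()` returns `path` invisibly; `read_event_log()`
#'   returns the event log tibble. Reading rejects malformed rows (naming
#'   the line), rejects records with no channel flag set, and re-sorts
#'   non-monotone timestamps stably with a warning.
#' @export
write_event_log <- function(log, path) {
  validate_event_log(log)
  out <- log
  out$datetime <- format(log$datetime, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!identical(names(raw), log_columns)) {
    abort(paste0("Unexpected header in ", path, "; expected ",
                 paste(log_columns, collapse = ",")))
  }
  prob <- readr::problems(raw)
  if (nrow(prob)) {
    abort(sprintf("Malformed row at line %d of %s.", prob$row[1] + 1, path))
  }
  dt <- as.POSIXct(raw$datetime, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  num <- suppressWarnings(
    lapply(raw[-1], function(x) as.integer(x))
  )
  bad <- which(is.na(dt) | Reduce(`|`, lapply(num, is.na)))
  if (length(bad)) {
    abort(sprintf("Malformed row at line %d of %s.", bad[1] + 1, path))
  }
  log <- dplyr::bind_cols(tibble(datetime = dt), as_tibble(num))
  validate_event_log(log)
  if (is.unsorted(as.numeric(log$datetime))) {
    warn("Timestamps are not monotone; records re-sorted stably.")
    log <- log[order(as.numeric(log$datetime)), ]
  }
  log
}

#' Per-minute activity counts for one channel
#'
#' The instrument's standard output measure: detector activations per
#' wall-clock minute. Minutes without records count 0.
#'
#' @param log an event log tibble.
#' @param channel channel index 1-6.
#' @param span optional POSIXct length-2 vector delimiting the minute grid;
#'   defaults to the span of the log (floored/ceiled to whole minutes).
#' @return tibble with columns `minute` (POSIXct bin start) and `count`.
#' @export
activity_per_minute <- function(log, channel, span = NULL) {
  validate_event_log(log)
  if (!is.numeric(channel) || !channel %in% 1:6) abort("Unknown channel.")
  col <- paste0("ch", channel)
  if (is.null(span)) {
    if (!nrow(log)) abort("Empty log needs an explicit `span`.")
    span <- range(log$datetime)
  }
  t0 <- as.numeric(span[1]) %/% 60 * 60
  t1 <- ceiling(as.numeric(span[2]) / 60) * 60
  if (t1 <= t0) t1 <- t0 + 60
  edges <- seq(t0, t1 - 60, by = 60)
  hit <- log$datetime[log[[col]] == 1L]
  idx <- (as.numeric(hit) - t0) %/% 60 + 1
  idx <- idx[idx >= 1 & idx <= length(edges)]
  tibble(minute = as.POSIXct(edges, tz = "UTC"),
         count = tabulate(idx, nbins = length(edges)))
}
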