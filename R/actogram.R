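#' Bin activity onto a regular day-aligned grid
#'
#' Counts records (or trace events) per half-open bin on a grid aligned to
#' midnight of the first day, the layout actogram rows require. The bin
#' width must divide 24 h evenly so rows tile days.
#'
#' @param x an event log tibble (give `channel`) or an activity trace
#'   (tibble with `time_s`, seconds since schedule start at midnight).
#' @param channel channel index 1-6 for event logs.
#' @param bin_width_s bin width in seconds (default 3600).
#' @param days number of days on the grid; defaults to the whole days
#'   covering the data.
#' @param animal_id label; defaults to the trace's `animal_id` or
#'   `"ch<channel>"`.
#' @return tibble of class `binned_activity` with columns `animal_id`,
#'   `day` (1-based), `hour` (bin start, hours since midnight),
#'   `bin_start_s` and `count`; all bins present, zero-filled.
#' @export
bin_activity <- function(x, channel = NULL, bin_width_s = 3600,
                         days = NULL, animal_id = NULL) {
  if (86400 %% bin_width_s != 0) {
    abort("`bin_width_s` must divide 24 h evenly so actogram rows tile days.")
  }
  if (is.data.frame(x) && "datetime" %in% names(x)) {
    validate_event_log(x)
    if (is.null(channel)) abort("Give `channel` to bin an event log.")
    col <- paste0("ch", channel)
    dt <- as.numeric(x$datetime[x[[col]] == 1L])
    start <- if (length(dt)) min(as.numeric(x$datetime)) %/% 86400 * 86400
             else 0
    t <- dt - start
    if (is.null(animal_id)) animal_id <- paste0("ch", channel)
  } else {
    t <- event_times_of(x)
    if (is.null(animal_id)) {
      animal_id <- if (is.data.frame(x) && "animal_id" %in% names(x) && nrow(x))
        x$animal_id[1] else "animal"
    }
  }
  if (is.null(days)) days <- max(1, ceiling(max(t, 0) / 86400))
  n_bins <- days * 86400 / bin_width_s
  idx <- floor(t / bin_width_s) + 1
  idx <- idx[idx >= 1 & idx <= n_bins]
  bin_start <- (seq_len(n_bins) - 1) * bin_width_s
  out <- tibble(
    animal_id = animal_id,
    day = floor(bin_start / 86400) + 1L,
    hour = (bin_start %% 86400) / 3600,
    bin_start_s = bin_start,
    count = tabulate(idx, nbins = n_bins)
  )
  class(out) <- c("binned_activity", class(out))
  attr(out, "bin_width_s") <- bin_width_s
  out
}

bin_width_of <- function(binned) {
  bw <- attr(binned, "bin_width_s")
  if (is.null(bw)) {
    bw <- sort(unique(binned$bin_start_s))
    bw <- if (length(bw) > 1) bw[2] - bw[1] else 86400
  }
  bw
}

#' Group actogram: per-bin mean and SEM across animals
#'
#' Animals (rows of identical grids) are averaged elementwise per
#' day x bin cell; the SEM is the across-animal standard deviation divided
#' by `sqrt(n)`. With a single animal the SEM is undefined and reported as
#' 0 with a warning.
#'
#' @param binned one or more binned-activity tables: a list, or a single
#'   row-bound tibble containing several `animal_id`s.
#' @return tibble of class `group_actogram` with `day`, `hour`,
#'   `bin_start_s`, `mean`, `sem`, `n_animals`.
#' @export
group_actogram <- function(binned) {
  if (is.data.frame(binned)) binned <- list(binned)
  all <- bind_rows(binned)
  grids <- split(all$bin_start_s, all$animal_id)
  if (length(unique(lapply(grids, unname))) != 1) {
    abort("All animals must share an identical bin grid.")
  }
  n <- length(grids)
  if (n == 1) warn("Single animal: SEM is undefined and reported as 0.")
  out <- all %>%
    group_by(.data$day, .data$hour, .data$bin_start_s) %>%
    summarise(mean = mean(.data$count),
              sem = if (n() > 1) sd(.data$count) / sqrt(n()) else 0,
              n_animals = n(), .groups = "drop") %>%
    arrange(.data$bin_start_s)
  class(out) <- c("group_actogram", class(out))
  attr(out, "bin_width_s") <- bin_width_of(bind_rows(binned))
  out
}

#' Daily activity totals
#'
#' Per-day sum of binned counts; a partial trailing day (incomplete bin
#' set) is excluded and reported via a message.
#'
#' @param binned a [bin_activity()] table.
#' @return tibble with `animal_id`, `day`, `total`.
#' @export
daily_totals <- function(binned) {
  bw <- bin_width_of(binned)
  per_day <- 86400 / bw
  out <- binned %>%
    group_by(.data$animal_id, .data$day) %>%
    summarise(total = sum(.data$count), n_bins = n(), .groups = "drop")
  partial <- out$n_bins < per_day
  if (any(partial)) {
    message(sum(partial), " partial day(s) excluded from daily totals.")
    out <- out[!partial, ]
  }
  out %>% dplyr::select(-"n_bins")
}

#' Activity within a daily clock window
#'
#' Per-day sum over the bins of a fixed clock-time window (e.g. the 2 AM -
#' 8 AM, 8 AM - 2 PM and 2 PM - 8 PM analysis windows). The window must be
#' aligned to bin edges.
#'
#' @param binned a [bin_activity()] table.
#' @param window numeric length-2, clock hours `c(start, end)` with
#'   `0 <= start < end <= 24`.
#' @return tibble with `animal_id`, `day`, `count`.
#' @export
window_activity <- function(binned, window) {
  bw_h <- bin_width_of(binned) / 3600
  if (length(window) != 2 || window[1] >= window[2] ||
      window[1] < 0 || window[2] > 24) {
    abort("`window` must be clock hours c(start, end) within one day.")
  }
  if (any(window %% bw_h != 0)) {
    abort("`window` must be aligned to bin edges.")
  }
  binned %>%
    filter(.data$hour >= window[1], .data$hour < window[2]) %>%
    group_by(.data$animal_id, .data$day) %>%
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Light-cycle modulation of activity
#'
#' For every light/dark transition of the schedule, the activity of the
#' first `window_h` hours after the change is normalized to the activity
#' of the `window_h` hours before it: `100 * post / pre` percent. A
#' pre-window with zero counts yields an undefined (NA) entry rather than
#' a division. Transitions without a full window of data on both sides are
#' dropped.
#'
#' @param x event times: activity trace, numeric vector (seconds), or
#'   event log (give `channel`).
#' @param schedule the [light_schedule()] driving the experiment.
#' @param window_h window length in hours (default 3).
#' @param channel channel index for event logs.
#' @param span_s optional numeric length-2 data span in seconds; defaults
#'   to `c(0, max time rounded up to a whole day)`.
#' @return tibble with `time_h`, `to_state`, `pre`, `post`,
#'   `modulation_pct`.
#' @export
light_modulation <- function(x, schedule, window_h = 3, channel = NULL,
                             span_s = NULL) {
  t <- event_times_of(x, channel)
  if (is.data.frame(x) && "datetime" %in% names(x)) {
    t <- t - min(as.numeric(x$datetime)) %/% 86400 * 86400
  }
  if (is.null(span_s)) span_s <- c(0, ceiling(max(t, 0) / 86400) * 86400)
  w <- window_h * 3600
  tr <- light_transitions(schedule, span_s[1] / 3600, span_s[2] / 3600)
  tr <- tr %>% filter(.data$time_h * 3600 - w >= span_s[1],
                      .data$time_h * 3600 + w <= span_s[2])
  ts <- tr$time_h * 3600
  pre <- vapply(ts, function(tt) sum(t >= tt - w & t < tt), numeric(1))
  post <- vapply(ts, function(tt) sum(t >= tt & t < tt + w), numeric(1))
  tr %>%
    mutate(pre = pre, post = post,
           modulation_pct = ifelse(pre > 0, 100 * post / pre, NA_real_))
}

#' Average daily activity profile over selected days
#'
#' @param binned a [bin_activity()] table.
#' @param days which days to average (default all).
#' @return tibble with `hour` and `count` (mean across the selected days
#'   and any animals present).
#' @export
daily_profile <- function(binned, days = NULL) {
  if (!is.null(days)) binned <- binned %>% filter(.data$day %in% days)
  binned %>%
    group_by(.data$hour) %>%
    summarise(count = mean(.data$count), .groups = "drop") %>%
    arrange(.data$hour)
}

#' Estimate a phase shift by circular cross-correlation
#'
#' Rotates the pre profile through all circular shifts of the daily grid
#' and returns the shift maximizing the Pearson correlation with the post
#' profile, in hours within (-12, 12]. Sign convention: negative = advance
#' (activity moves to an earlier clock time). Ties are broken toward the
#' smallest absolute shift.
#'
#' @param pre,post daily profiles on the same circular grid: numeric
#'   vectors of per-bin counts, or [daily_profile()] tibbles.
#' @return one-row tibble with `shift_h` and `correlation`.
#' @export
estimate_phase_shift <- function(pre, post) {
  p <- if (is.data.frame(pre)) pre$count else as.numeric(pre)
  q <- if (is.data.frame(post)) post$count else as.numeric(post)
  n <- length(p)
  if (length(q) != n) abort("Profiles must share one circular grid.")
  if (sd(p) == 0 || sd(q) == 0) {
    abort("Flat profile: phase shift undefined.")
  }
  bw_h <- 24 / n
  ks <- seq_len(n) - 1
  shift_h <- wrap_half_day(ks * bw_h)
  corr <- vapply(ks, function(k) {
    # candidate: post[h] = pre[h - k]  (k bins of delay; advance negative)
    rot <- p[((seq_len(n) - 1 - k) %% n) + 1]
    cor(q, rot)
  }, numeric(1))
  ord <- order(abs(shift_h), shift_h)
  best <- ord[which.max(corr[ord])]
  tibble(shift_h = shift_h[best], correlation = corr[best])
}
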