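#' Define a light/dark schedule with optional phase shifts
#'
#' A schedule is a two-valued (light/dark) function of time with two
#' transitions per cycle. Time is measured in hours from the start of the
#' recording, with hour 0 at midnight of day 1, so clock times and elapsed
#' hours coincide on day 1. The default reproduces an inverted 12 h/12 h
#' housing cycle with lights ON at 8 PM and OFF at 8 AM.
#'
#' Phase shifts move every transition *strictly after* their effective time
#' by the signed offset, so a shift takes hold at the first affected
#' transition and shortens (or lengthens) the phase in progress. A -6 h
#' advance effective at the dark onset of day 3 therefore shortens that
#' day's dark period from 12 h to 6 h, after which lights run 6 h earlier.
#'
#' @param light_on,light_off clock times (`"HH:MM"` or numeric hours) at
#'   which lights switch on/off each cycle.
#' @param shifts optional data frame with columns `time_h` (effective time
#'   in hours since schedule start, strictly increasing) and `offset_h`
#'   (signed shift in hours; negative = advance). Build rows conveniently
#'   with [schedule_shift()].
#' @param cycle_length cycle length in hours (default 24).
#' @return an object of class `light_schedule`.
#' @examples
#' sch <- light_schedule("20:00", "08:00",
#'                       shifts = schedule_shift(day = 3, at = "08:00",
#'                                               offset_h = -6))
#' light_state(sch, c(9, 21))
#' @export
light_schedule <- function(light_on = "20:00", light_off = "08:00",
                           shifts = NULL, cycle_length = 24) {
  on_h <- parse_clock(light_on)
  off_h <- parse_clock(light_off)
  if (cycle_length <= 0) abort("`cycle_length` must be positive.")
  if (isTRUE(all.equal(on_h, off_h))) {
    abort("`light_on` and `light_off` must differ.")
  }
  if (on_h >= cycle_length || off_h >= cycle_length) {
    abort("Clock times must lie within one cycle.")
  }
  if (is.null(shifts)) {
    shifts <- tibble(time_h = numeric(), offset_h = numeric())
  } else {
    shifts <- as_tibble(shifts)
    if (!all(c("time_h", "offset_h") %in% names(shifts))) {
      abort("`shifts` needs columns `time_h` and `offset_h`.")
    }
    shifts <- shifts[c("time_h", "offset_h")]
    if (is.unsorted(shifts$time_h, strictly = TRUE)) {
      abort("Shift effective times must be strictly increasing.")
    }
  }
  structure(
    list(cycle_length = cycle_length, light_on_h = on_h,
         light_off_h = off_h, shifts = shifts),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> %g h cycle, lights ON %05.2f h, OFF %05.2f h\n",
              x$cycle_length, x$light_on_h, x$light_off_h))
  if (nrow(x$shifts)) {
    cat(sprintf("  shift of %+g h effective at %g h\n",
                x$shifts$offset_h, x$shifts$time_h), sep = "")
  }
  invisible(x)
}

#' Specify a schedule shift by day and clock time
#'
#' @param day 1-based day index at which the shift becomes effective.
#' @param at clock time on that day (`"HH:MM"` or numeric hours).
#' @param offset_h signed offset in hours (negative = advance).
#' @return one-row tibble suitable for the `shifts` argument of
#'   [light_schedule()].
#' @export
schedule_shift <- function(day, at = "08:00", offset_h) {
  tibble(time_h = (day - 1) * 24 + parse_clock(at), offset_h = offset_h)
}

# is clock-hour h lit under the unshifted cycle? half-open [on, off)
base_is_light <- function(schedule, h) {
  on <- schedule$light_on_h
  off <- schedule$light_off_h
  if (on < off) h >= on & h < off else h >= on | h < off
}

#' List light/dark transitions within a time span
#'
#' Transition instants belong to the new state (half-open intervals). Across
#' a shift event one phase may be shortened, but directions still alternate
#' for offsets smaller than a half cycle.
#'
#' @param schedule a [light_schedule()].
#' @param from_h,to_h span in hours since schedule start; transitions with
#'   `from_h <= time < to_h` are returned.
#' @return tibble with columns `time_h` and `to_state`
#'   (`"light"` or `"dark"`), strictly increasing in time.
#' @export
light_transitions <- function(schedule, from_h, to_h) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (to_h <= from_h) {
    return(tibble(time_h = numeric(), to_state = character()))
  }
  cl <- schedule$cycle_length
  max_off <- if (nrow(schedule$shifts)) sum(abs(schedule$shifts$offset_h)) else 0
  k <- seq.int(floor((min(from_h, 0) - max_off) / cl) - 1,
               ceiling((to_h + max_off) / cl) + 1)
  base <- tibble(
    time_h = c(k * cl + schedule$light_on_h, k * cl + schedule$light_off_h),
    to_state = rep(c("light", "dark"), each = length(k))
  )
  # cumulative offset from all shifts strictly before each base transition
  if (nrow(schedule$shifts)) {
    off <- vapply(base$time_h, function(tt) {
      sum(schedule$shifts$offset_h[schedule$shifts$time_h < tt])
    }, numeric(1))
    base$time_h <- base$time_h + off
  }
  out <- base %>% arrange(.data$time_h) %>%
    filter(.data$time_h >= from_h, .data$time_h < to_h)
  if (is.unsorted(out$time_h, strictly = TRUE)) {
    abort("Shift offsets exceed a phase length; transitions out of order.")
  }
  out
}

#' Light state at given times
#'
#' @param schedule a [light_schedule()].
#' @param time_h times in hours since schedule start (vectorized).
#' @return character vector, `"light"` or `"dark"`. Transition instants
#'   belong to the new state.
#' @export
light_state <- function(schedule, time_h) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (any(time_h < 0)) abort("Times before the schedule start are undefined.")
  init_light <- base_is_light(schedule, 0)
  if (!length(time_h)) return(character())
  tr <- light_transitions(schedule, 0, max(time_h) + 1e-9)
  tr <- tr[tr$time_h > 0, ] # a transition exactly at 0 is the initial state
  nflip <- findInterval(time_h, tr$time_h) # counts transitions <= t
  ifelse(xor(init_light, nflip %% 2 == 1), "light", "dark")
}
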