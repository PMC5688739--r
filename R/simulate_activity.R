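#' Strain activity profiles
#'
#' A strain profile parameterizes the circadian event generator: Doppler
#' motion events are drawn from an inhomogeneous Poisson process whose rate
#' is `rate_active` events/s while the animal's *internal* circadian phase
#' says "subjective dark" and `rate_rest` otherwise, both multiplied by
#' `activity_scale`. The internal phase (clock hour of subjective dark
#' onset) is corrected once per day toward the schedule's dark onset by
#' `entrainment_rate` times the remaining signed error (wrapped to
#' (-12, 12] h, so a -6 h advance is corrected as an advance).
#'
#' `cd1_profile()` and `lab_profile()` bundle the package's calibration for
#' an outbred control strain and a hyperactive, photoentrainment-deficient
#' line: identical event rates, a two-fold activity scale for the
#' hyperactive line (reproducing its roughly doubled daily activity), an
#' entrainment rate of 0.8/day for the control (re-entrainment essentially
#' complete within two days of a 6 h advance) and 0 for the deficient line
#' (no photoentrainment). These are calibration choices, documented in the
#' methods vignette.
#'
#' @param name label carried into simulated traces.
#' @param rate_active,rate_rest event rates (events/s) in subjective dark
#'   and subjective light; `rate_active > rate_rest >= 0`.
#' @param activity_scale positive multiplier applied to both rates.
#' @param entrainment_rate fraction in `[0, 1]` of the remaining phase
#'   error corrected per day.
#' @param phase0 initial internal phase: clock hour of subjective dark
#'   onset (default 8, i.e. entrained to a dark phase starting 8 AM).
#' @return object of class `strain_profile`.
#' @export
strain_profile <- function(name, rate_active = 0.5, rate_rest = 0.05,
                           activity_scale = 1, entrainment_rate = 0.8,
                           phase0 = 8) {
  if (!(rate_active >= rate_rest && rate_rest >= 0) || rate_active <= 0) {
    abort("Need rate_active >= rate_rest >= 0 and rate_active > 0.")
  }
  if (entrainment_rate < 0 || entrainment_rate > 1) {
    abort("`entrainment_rate` must lie in [0, 1].")
  }
  if (activity_scale <= 0) abort("`activity_scale` must be positive.")
  structure(
    list(name = name, rate_active = rate_active, rate_rest = rate_rest,
         activity_scale = activity_scale, entrainment_rate = entrainment_rate,
         phase0 = phase0 %% 24),
    class = "strain_profile"
  )
}

#' @rdname strain_profile
#' @export
cd1_profile <- function() {
  strain_profile("CD1", rate_active = 0.5, rate_rest = 0.05,
                 activity_scale = 1, entrainment_rate = 0.8)
}

#' @rdname strain_profile
#' @export
lab_profile <- function() {
  strain_profile("LAB", rate_active = 0.5, rate_rest = 0.05,
                 activity_scale = 2, entrainment_rate = 0)
}

# clock hour of the next dark onset at/after each day start; carries the
# previous target forward when a day contains none
dark_onset_targets <- function(schedule, n_days) {
  tr <- light_transitions(schedule, 0, (n_days + 2) * 24)
  onsets <- tr$time_h[tr$to_state == "dark"]
  if (!length(onsets)) abort("Schedule has no dark onset; cannot entrain.")
  vapply(seq_len(n_days), function(d) {
    nxt <- onsets[onsets >= (d - 1) * 24]
    if (length(nxt)) nxt[1] %% 24 else onsets[length(onsets)] %% 24
  }, numeric(1))
}

# per-day internal phase trajectory of the proportional-correction model
entrain_phases <- function(profile, schedule, n_days) {
  target <- dark_onset_targets(schedule, n_days)
  p <- numeric(n_days)
  p[1] <- profile$phase0
  if (n_days > 1) {
    for (d in 2:n_days) {
      err <- wrap_half_day(target[d] - p[d - 1])
      p[d] <- (p[d - 1] + profile$entrainment_rate * err) %% 24
    }
  }
  tibble(day = seq_len(n_days), phase_h = p, target_h = target)
}

#' Simulate a circadian motion-event trace for one animal
#'
#' Events are drawn by thinning: a homogeneous Poisson stream at the
#' maximum rate is generated over the span and each candidate is kept with
#' probability `rate(t)/rate_max`, where the rate is piecewise constant at
#' `rate_active` during the animal's subjective dark half-cycle (internal
#' phase to phase + 12 h, clock time) and `rate_rest` otherwise, both
#' scaled by `activity_scale`. The internal phase follows the per-day
#' proportional entrainment model described in [strain_profile()].
#'
#' @param profile a [strain_profile()].
#' @param schedule a [light_schedule()] covering the span.
#' @param days number of simulated days; alternatively give `duration_s`.
#' @param seed integer seed; fixed seed gives a bit-identical trace.
#' @param duration_s span length in seconds (default `days * 86400`).
#' @param animal_id label (default the profile name).
#' @return tibble with columns `animal_id`, `time_s` (strictly increasing
#'   event times in seconds since schedule start), carrying the per-day
#'   phase trajectory in attribute `"phases"` and the seed in `"seed"`.
#' @export
simulate_mouse <- function(profile, schedule, days = 6, seed,
                           duration_s = days * 86400,
                           animal_id = profile$name) {
  stopifnot(inherits(profile, "strain_profile"),
            inherits(schedule, "light_schedule"))
  if (duration_s <= 0) abort("Simulation span must be non-empty.")
  n_days <- ceiling(duration_s / 86400)
  phases <- entrain_phases(profile, schedule, n_days)

  set.seed(seed)
  lam_max <- profile$rate_active * profile$activity_scale
  n_cand <- rpois(1, lam_max * duration_s)
  cand <- sort(runif(n_cand, 0, duration_s))
  day <- pmin(floor(cand / 86400) + 1, n_days)
  h <- (cand %% 86400) / 3600
  in_subjective_dark <- ((h - phases$phase_h[day]) %% 24) < 12
  rate <- ifelse(in_subjective_dark, profile$rate_active, profile$rate_rest) *
    profile$activity_scale
  keep <- runif(n_cand) < rate / lam_max
  times <- unique(cand[keep])

  out <- tibble(animal_id = animal_id, time_s = times)
  attr(out, "phases") <- phases
  attr(out, "seed") <- seed
  out
}

#' Simulate an analog-clock validation event stream
#'
#' Emulates a ticking clock hand observed by the detector: nominal events
#' every `tick_interval` seconds. A sinusoidal term of amplitude
#' `mod_amplitude` and period `mod_period` perturbs the tick *intervals*
#' (emulating a periodic mechanical wobble of the hand), Gaussian jitter of
#' sd `jitter_sd` perturbs the recorded timestamps, and each tick is
#' dropped independently with probability `miss_prob`. The output is
#' sorted and de-duplicated, hence strictly increasing; with all noise at
#' zero it is exactly the tick grid.
#'
#' @param duration_s recording length in seconds.
#' @param tick_interval nominal tick spacing in seconds (default 1).
#' @param jitter_sd timestamp jitter sd in seconds.
#' @param miss_prob probability in `[0, 1)` that a tick goes undetected.
#' @param mod_period,mod_amplitude period (s) and amplitude (s) of the
#'   sinusoidal interval modulation; amplitude 0 disables it.
#' @param seed integer seed.
#' @return tibble with column `time_s`.
#' @export
simulate_clock <- function(duration_s = 1800, tick_interval = 1,
                           jitter_sd = 0, miss_prob = 0,
                           mod_period = 60, mod_amplitude = 0, seed = 1) {
  if (duration_s <= 0 || tick_interval <= 0) {
    abort("`duration_s` and `tick_interval` must be positive.")
  }
  if (miss_prob < 0 || miss_prob >= 1) abort("`miss_prob` must be in [0, 1).")
  if (mod_amplitude < 0 || jitter_sd < 0) abort("Noise amplitudes must be >= 0.")
  if (mod_amplitude > 0 && mod_period <= 0) {
    abort("`mod_period` must be positive when modulation is on.")
  }
  set.seed(seed)
  n <- floor(duration_s / tick_interval)
  iv <- rep(tick_interval, n)
  if (mod_amplitude > 0) {
    iv <- iv + mod_amplitude * sin(2 * pi * seq_len(n) * tick_interval / mod_period)
  }
  times <- cumsum(iv)
  if (jitter_sd > 0) times <- times + rnorm(n, 0, jitter_sd)
  if (miss_prob > 0) times <- times[runif(n) >= miss_prob]
  tibble(time_s = unique(sort(times)))
}
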