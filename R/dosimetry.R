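#' Microwave exposure specification
#'
#' Parameters of the pulsed X-band emitter for the dosimetry chain. The
#' defaults describe the detector module used by the monitor: maximal
#' EIRP 14 dBm, pulsed at 1.34 kHz with 25 microsecond pulses, and a
#' worst-case animal-to-sensor distance of 2 cm.
#'
#' @param eirp_dbm effective isotropic radiated power in dBm.
#' @param distance_m distance to the target in meters (> 0).
#' @param pulse_rate pulse repetition rate in Hz (> 0).
#' @param pulse_width pulse duration in seconds, with
#'   `0 <= pulse_width < 1 / pulse_rate`.
#' @return object of class `exposure_spec`.
#' @export
exposure_spec <- function(eirp_dbm = 14, distance_m = 0.02,
                          pulse_rate = 1340, pulse_width = 25e-6) {
  if (distance_m <= 0) abort("`distance_m` must be positive.")
  if (pulse_rate <= 0) abort("`pulse_rate` must be positive.")
  if (pulse_width < 0 || pulse_width >= 1 / pulse_rate) {
    abort("`pulse_width` must lie in [0, 1/pulse_rate).")
  }
  structure(list(eirp_dbm = eirp_dbm, distance_m = distance_m,
                 pulse_rate = pulse_rate, pulse_width = pulse_width),
            class = "exposure_spec")
}

#' Convert dBm to milliwatts
#'
#' @param dbm power in dBm.
#' @return power in mW: `10^(dbm/10)`.
#' @export
dbm_to_mw <- function(dbm) 10^(dbm / 10)

#' Far-field power density
#'
#' Spreads the EIRP over a sphere: `S = EIRP / (4 pi R^2)`, converted to
#' mW/cm^2. This far-field formula over-predicts the density in the near
#' field and is used deliberately as a worst-case (conservative) estimate;
#' no near-field correction is applied.
#'
#' @param eirp_mw radiated power in mW.
#' @param distance_m distance in meters (> 0).
#' @return power density in mW/cm^2.
#' @export
power_density <- function(eirp_mw, distance_m) {
  if (any(distance_m <= 0)) abort("`distance_m` must be positive.")
  r_cm <- distance_m * 100
  eirp_mw / (4 * pi * r_cm^2)
}

#' Duty cycle of a pulsed emitter
#'
#' @param pulse_rate pulse repetition rate in Hz.
#' @param pulse_width pulse duration in seconds.
#' @return fraction of time the emitter is on (`pulse_rate * pulse_width`);
#'   a product of 1 or more is an error.
#' @export
duty_cycle <- function(pulse_rate, pulse_width) {
  d <- pulse_rate * pulse_width
  if (any(d >= 1)) abort("Duty cycle must be < 1.")
  if (any(d < 0)) abort("Duty cycle must be >= 0.")
  d
}

#' Time-averaged power density of a pulsed emitter
#'
#' Continuous-wave far-field density scaled by the duty cycle.
#'
#' @param spec an [exposure_spec()].
#' @return time-averaged power density in mW/cm^2.
#' @export
time_avg_density <- function(spec) {
  stopifnot(inherits(spec, "exposure_spec"))
  power_density(dbm_to_mw(spec$eirp_dbm), spec$distance_m) *
    duty_cycle(spec$pulse_rate, spec$pulse_width)
}

#' One-row dosimetry report
#'
#' @param spec an [exposure_spec()].
#' @param reference_density optional reference density in mW/cm^2 to
#'   compare against (adds a `ratio_to_reference` column).
#' @return tibble with `eirp_mw`, `cw_density_mw_cm2`, `duty`,
#'   `avg_density_mw_cm2` (and optionally `ratio_to_reference`).
#' @export
dosimetry_report <- function(spec, reference_density = NULL) {
  stopifnot(inherits(spec, "exposure_spec"))
  eirp_mw <- dbm_to_mw(spec$eirp_dbm)
  cw <- power_density(eirp_mw, spec$distance_m)
  duty <- duty_cycle(spec$pulse_rate, spec$pulse_width)
  out <- tibble(eirp_mw = eirp_mw, cw_density_mw_cm2 = cw, duty = duty,
                avg_density_mw_cm2 = cw * duty)
  if (!is.null(reference_density)) {
    out$ratio_to_reference <- out$avg_density_mw_cm2 / reference_density
  }
  out
}
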