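---
title: "Models and methods behind cagewatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cagewatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagewatch)
```

# The system being modeled

Microwave Doppler (X-band) motion detectors mounted outside a home cage
register every movement of the animal inside: reflected 10.5 GHz waves are
frequency-shifted by the moving body, and the detector emits short logic
pulses. An interface board stretches these microsecond pulses to
retriggerable pulses of at least one second, an interrupt-driven
microcontroller polls up to six channels, and each interrupt is written to
a CSV log with a real-time-clock timestamp, six channel flags and an
ambient-light reading. cagewatch implements this chain as an explicit,
testable model, together with the analyses such recordings feed: interval
statistics for instrument validation, actograms and photoentrainment
statistics for circadian experiments, a pixel-difference video scorer used
as an unbiased comparison method, and far-field dosimetry for the emitter.

Everything downstream is driven by a synthetic-data generator, so every
stage can be exercised end to end without hardware.

# Light schedules

A `light_schedule()` is a two-valued function of time with two transitions
per cycle. Conventions, chosen for unambiguous binning:

* intervals are half-open: a transition instant belongs to the **new**
  state;
* time zero is midnight of day 1, so clock hours and elapsed hours agree
  on day 1;
* a phase shift moves all transitions *strictly after* its effective time
  by the signed offset, so it is realized at the first affected
  transition and shortens (or stretches) the phase in progress.

The bundled circadian protocol is an inverted 12 h/12 h cycle (lights ON
20:00, OFF 08:00) whose −6 h advance is effective at the dark onset of
day 3: day 3's dark period shrinks from 12 h to 6 h (08:00–14:00), after
which lights run 14:00–02:00. The housing literature gives both the
lights-ON and lights-OFF clock conventions; both are settable, and the
defaults follow the experimental protocol above.

# Synthetic circadian activity

Events are an inhomogeneous Poisson process with a two-level rate:
`rate_active` (default 0.5 events/s) while the animal's *internal* phase
says "subjective dark", `rate_rest` (default 0.05 events/s) otherwise,
both multiplied by `activity_scale`. Sampling uses thinning against the
maximum rate, which is exact for a piecewise-constant rate and trivially
reproducible under a fixed seed.

Photoentrainment is modeled at day resolution, the resolution at which
re-entrainment is observed in actograms: the internal phase `p` (clock
hour of subjective dark onset) is corrected once per day,

```
p[d] = p[d-1] + r * wrap(target[d] - p[d-1]),   wrap into (-12, 12] h,
```

where `target[d]` is the clock hour of the next dark onset at or after
the start of day `d`, and `r` is `entrainment_rate`. The wrap to
(−12, 12] makes a −6 h advance be corrected as an advance. With `r = 1`
the phase equals the schedule phase from day 2 onward, exactly; with
`r = 0` the animal ignores light entirely.

## Calibration of the bundled profiles

* **Control (CD1-like)**: `activity_scale = 1`, `entrainment_rate = 0.8`.
* **Hyperactive, entrainment-deficient (LAB-like)**: `activity_scale = 2`
  (reproducing the roughly doubled daily activity of the hyperactive
  line), `entrainment_rate = 0` (no photoentrainment).

The control entrainment rate deserves a note, because it is the one
genuinely free parameter. Under the day-resolution correction model the
residual phase error after the −6 h advance at day 3 is
`6 * (1 - r)^(d - 3)` hours on day `d`. The recovery analysis compares
days 1–2 against days 5–6 on a 1 h grid by circular cross-correlation,
which resolves the shift to the nearest hour: the days 5–6 residual must
therefore stay well below half a bin. At `r = 0.8` the residuals are 0.24 h
and 0.05 h (recovered shift −6 h, robustly); at, say, `r = 0.6` they
would be 0.96 h and 0.38 h, and the estimator would systematically report
−5 h — a property of the estimator's quantization, not of the biology.
`r = 0.8` encodes the observation that control animals re-entrain to an
advance of this size within about two days. It is a calibration choice,
made once from this closed-form argument, not a fitted value.

The generator does **not** model ultradian bout structure, activity
onset anticipation, masking by light, or sleep homeostasis. Passing tests
therefore show that the *analyses* behave correctly on data with the
assumed two-state Poisson structure; they do not validate the biology of
real recordings.

# The detector-to-logger model

`extend_pulses()` is the retriggerable monostable: output-high intervals
are the union of `[t, t + hold)` over events, `hold` defaulting to 1 s.

`log_events()` merges per-channel event streams (after applying
crosstalk, below) and walks them sequentially. An event arriving at least
`dead_time` after the previous written record raises an interrupt and
produces one record; its flags are the channels with an event in
`(max(previous record time, t - hold), t]` — the monostables are polled
at the interrupt and *reset after every write*, so flag windows never
reach behind the previous record. `dead_time` (default 0.1 s) is a
declared model parameter standing in for the storage-write duration,
which the firmware's documentation does not pin down; it makes the
one-record-per-interrupt versus burst-coalescing behavior explicit and
tunable. Timestamps are floored (not rounded) to whole seconds, the usual
real-time-clock read semantics, so tests can be exact.

Crosstalk is per physical event and independent per neighbor channel:
event in cage *i*, picked up on channel *j* with probability
`crosstalk[i, j]`. A shield between two cages forces the pair's pickup to
zero — the aluminum-sheet experiment shows complete elimination, so a
probabilistic attenuation model is not needed. With this record/reset
semantics the ratio of neighbor flags to source flags recovers the pickup
probability almost unbiasedly (the residual bias is of order
`rate * dead_time * p`, under 1 percentage point at 0.5 events/s); a
lookback window without reset would inflate a 26% pickup to ~35% at these
rates.

The CSV schema is fixed: header `datetime,ch1,...,ch6,light`, datetime as
`YYYY-MM-DD HH:MM:SS` (UTC), flags 0/1, light a 10-bit integer. Reading
validates flags (a record with no flag set cannot have been written by an
interrupt), names the line of a malformed row, and stably re-sorts
non-monotone timestamps with a warning. The round trip is lossless.

# Interval analysis

* **Summary**: arithmetic mean; percentiles by linear interpolation
  between order statistics (type 7), declared because percentile
  conventions differ.
* **Histogram**: half-open bins `[k w, (k+1) w)`, default 100 ms;
  `fraction_in_range()` is likewise half-open `[lo, hi)`.
* **Autocorrelation**: per-lag Pearson correlation over overlapping pairs
  rather than the FFT-based biased estimator — small-sample values stay
  bounded and interpretable, at O(n·max_lag) cost that is irrelevant at
  these sizes.
* **Dominant period**: lags above `min_lag` (default 10) whose
  correlation exceeds a white-noise band are grouped into contiguous
  runs, and the argmax within the first qualifying run is converted to
  time via the mean interval. Two numerical details matter. First, the
  band is lag-dependent, `band_factor / sqrt(n - k)`, because only
  `n - k` pairs enter the lag-`k` estimate; a flat `1/sqrt(n)` band lets
  large-lag noise through. Second, a run only qualifies if preceded by a
  sub-band lag: the autocorrelation of a sinusoidally modulated series is
  itself (to first order) a cosine in the lag, so the descending flank of
  the lag-0 peak can exceed the band just past `min_lag` and must not be
  read as a rhythm. Restricting to the first qualifying run also resolves
  the harmonic ambiguity of a global argmax (lags P, 2P, 3P share the
  same expected height). If no run qualifies the result is a "no rhythm"
  row, not an error.

The clock-stream generator mirrors the validation experiment: ticks at
1 s, Gaussian timestamp jitter, independent missed detections, and an
optional sinusoidal perturbation of the tick *intervals* emulating a
periodic mechanical wobble of the clock hand. Interval-domain modulation
is deliberate: modulating the timestamps instead would attenuate the
interval-domain amplitude by `2 sin(pi/P)` (about ×0.1 at P = 60 s) and
make the modulation undetectable at realistic jitter — inconsistent with
how such a wobble presents in recorded interval data.

# Actogram analyses

Binning is day-aligned (rows start at midnight, single-plotted;
double-plotting is an output option) and conserves counts; bin widths
must divide 24 h so rows tile days. Group actograms average across
animals per bin, with SEM = sd/√n across animals per bin (not across
days); n = 1 reports SEM 0 with a warning rather than NA, so plots
degrade gracefully.

The modulation statistic normalizes the activity of the first 3 h after
each light transition to the 3 h before it (`100 × post/pre` %); a zero
pre-window yields an undefined entry rather than a division. Counts are
raw record counts, the instrument's native unit. In group summaries of
the shift protocol, the shift day itself is excluded from baseline/post
comparisons (the bundled preset uses days 1–2 versus days 5–6).

`estimate_phase_shift()` correlates two daily profiles over all circular
rotations of the grid and returns the best shift in (−12, 12] h, ties
broken toward the smallest magnitude. Sign convention: negative =
advance (activity moves earlier). On a 1 h grid the estimator quantizes
to whole hours — the resolution/robustness trade-off discussed under
calibration above.

# Pixel-difference video scoring

A pixel counts as changed when its absolute gray-level difference between
consecutive frames is at least `pixel_delta_min` (default 10 on 8-bit;
some per-pixel floor is required to define "changed", and the default
sits above typical sensor noise). A frame pair scores motion when its
changed-pixel fraction strictly exceeds `frame_fraction_threshold`
(default 8.5%, a liberal threshold above a ~5.5% noise floor). Binary
motion is collapsed to 2 s bins (any motion → 1), then to 30 s bins as
percent of active fine bins — the grid on which methods are compared via
Pearson correlation and relative mean difference. Observer scores enter
as already-percent traces; no observer model is simulated.

The synthetic video calibrates its noise so the expected changed-pixel
fraction equals a target: each pixel is displaced by `noise_delta` gray
levels in a random subset of each frame with inclusion probability `q`,
giving a change probability of `2q(1-q)` per pixel pair, solved for `q`.
A bright square blob jumps between disjoint positions during scripted
motion epochs (at least one side length per frame, so each moving pair
changes ≈ twice the blob area) and rests at a home position otherwise;
the scripted per-30 s percentages are then recovered by the scorer within
one 2 s bin of quantization, which is the end-to-end oracle used in the
tests. Frame rate defaults to 10 Hz and frame size to 40×40 — small
enough to keep array fixtures cheap, large enough that blob and noise
fractions are well separated.

# Dosimetry

The chain is analytic: `10^(dBm/10)` to milliwatts; far-field spreading
`S = EIRP / (4 π R²)` reported in mW/cm² (the formula over-predicts in
the near field and is used deliberately as a worst case; no near-field
correction is applied); duty cycle `rate × width`; and time-averaged
density = CW density × duty. Defaults describe the detector module: 14
dBm EIRP, 2 cm worst-case distance, 1.34 kHz pulses of 25 µs (duty
0.0335), giving ≈ 0.50 mW/cm² CW and ≈ 0.0167 mW/cm² time-averaged.

# Presets, problem sizes and determinism

Three presets bundle the experiments: `clock-validation` (30 min of 1 s
ticks, 5 ms jitter, 2% misses; plus a modulated variant with 10 ms
interval modulation at 60 s), `crosstalk-shield` (30 min, cage 2 occupied
at 0.5 events/s, 26% pickup on the open neighbor, shield on the other
side), and `circadian-shift` (6 days, 4 control + 3 hyperactive animals,
the −6 h protocol, 1 h bins). These spans — 30-minute validation runs,
6-day circadian runs, 20-seed recovery ensembles — are the sizes at which
every statistic of interest is already stable, and they keep any full
reproduction in the range of seconds to a few minutes. Every random stage
takes an explicit seed, derived sub-seeds keep stages independent, and a
bundle written twice from the same config and seed is byte-identical; the
manifest (config, seed, hash) suffices to reproduce it.

# Known limitations

* The activity generator's two-state Poisson rate omits ultradian
  structure and light-masking; group differences it produces are by
  construction, so analyses are validated, not biological claims.
* Phase-shift recovery quantizes to the bin width; shifts that leave
  sub-bin residual errors need finer bins or more post-shift days.
* The logger model treats the dead time as constant; real SD-card writes
  vary.
* Period detection assumes a single dominant rhythm; closely spaced
  periods merge into one significant run.
* Dosimetry is far-field worst-case only — no SAR, antenna pattern or
  tissue model.
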