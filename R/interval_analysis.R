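#' Inter-event intervals
#'
#' Successive differences of event times, the basis of the detector
#' validation analyses. For an event log the 1 s logger timestamps are
#' used (so ties yield zero-length intervals); pass the high-resolution
#' simulated trace instead when sub-second precision matters.
#'
#' @param x an activity trace (tibble with `time_s`), a numeric vector of
#'   event times, or an event log tibble (then give `channel`).
#' @param channel channel index 1-6, required for event logs.
#' @return tibble with columns `index` and `interval_s`; `nrow` is one
#'   less than the number of events.
#' @export
event_intervals <- function(x, channel = NULL) {
  t <- event_times_of(x, channel)
  if (length(t) < 2) abort("Need at least two events to form intervals.")
  tibble(index = seq_len(length(t) - 1), interval_s = diff(t))
}

event_times_of <- function(x, channel = NULL) {
  if (is.numeric(x)) return(sort(as.numeric(x)))
  if (is.data.frame(x) && "time_s" %in% names(x)) return(sort(x$time_s))
  if (is.data.frame(x) && "datetime" %in% names(x)) {
    if (is.null(channel)) abort("Give `channel` to extract times from a log.")
    validate_event_log(x)
    col <- paste0("ch", channel)
    return(sort(as.numeric(x$datetime[x[[col]] == 1L])))
  }
  abort("Cannot interpret `x` as events; give a trace, log or time vector.")
}

intervals_of <- function(x) {
  if (is.data.frame(x) && "interval_s" %in% names(x)) x$interval_s
  else as.numeric(x)
}

#' Summary statistics of an interval series
#'
#' Arithmetic mean, median and requested percentiles (linear interpolation
#' between order statistics, type-7 convention).
#'
#' @param x interval series from [event_intervals()] (or numeric vector).
#' @param percentiles percentile levels in percent.
#' @return object of class `interval_summary`; see also [tidy()] and
#'   [glance()] methods.
#' @export
interval_summary <- function(x, percentiles = c(1, 5, 25, 50, 75, 95, 99)) {
  iv <- intervals_of(x)
  if (!length(iv)) abort("Empty interval series.")
  pct <- quantile(iv, percentiles / 100, type = 7, names = FALSE)
  structure(
    list(n_events = length(iv) + 1L, n_intervals = length(iv),
         mean = mean(iv), median = median(iv),
         percentiles = setNames(pct, paste0("p", percentiles))),
    class = "interval_summary"
  )
}

#' @export
print.interval_summary <- function(x, ...) {
  cat(sprintf("<interval_summary> %d events, %d intervals\n",
              x$n_events, x$n_intervals))
  cat(sprintf("  mean %.5f s, median %.3f s\n", x$mean, x$median))
  print(round(x$percentiles, 4))
  invisible(x)
}

#' Tidy an interval summary
#'
#' @param x an `interval_summary`.
#' @param ... unused.
#' @return `tidy()`: tibble of percentile levels and values;
#'   `glance()`: one-row tibble with `n_events`, `n_intervals`, `mean`,
#'   `median`.
#' @method tidy interval_summary
#' @export
tidy.interval_summary <- function(x, ...) {
  tibble(percentile = as.numeric(sub("^p", "", names(x$percentiles))),
         interval_s = unname(x$percentiles))
}

#' @rdname tidy.interval_summary
#' @method glance interval_summary
#' @export
glance.interval_summary <- function(x, ...) {
  tibble(n_events = x$n_events, n_intervals = x$n_intervals,
         mean = x$mean, median = x$median)
}

#' Interval histogram with fixed-width half-open bins
#'
#' @param x interval series or numeric vector.
#' @param bin_width bin width in seconds (default 0.1, i.e. 100 ms).
#' @return tibble with `bin_lo`, `bin_hi` (bins `[k*w, (k+1)*w)`) and
#'   `count`; zero-count bins between the extremes are included and counts
#'   sum to the series length.
#' @export
interval_histogram <- function(x, bin_width = 0.1) {
  iv <- intervals_of(x)
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  if (!length(iv)) abort("Empty interval series.")
  k <- floor(iv / bin_width)
  kk <- seq(min(k), max(k))
  tibble(bin_lo = kk * bin_width, bin_hi = (kk + 1) * bin_width,
         count = tabulate(k - min(k) + 1L, nbins = length(kk)))
}

#' Fraction of intervals in a half-open range
#'
#' @param x interval series or numeric vector.
#' @param lo,hi range bounds in seconds; counts intervals with
#'   `lo <= interval < hi`.
#' @return fraction in `[0, 1]`.
#' @export
fraction_in_range <- function(x, lo, hi) {
  iv <- intervals_of(x)
  if (!length(iv)) abort("Empty interval series.")
  if (lo >= hi) abort("Need `lo < hi`.")
  mean(iv >= lo & iv < hi)
}

#' Lagged autocorrelation of an interval series
#'
#' At lag `k` the Pearson correlation of the overlapping pairs
#' `(x_t, x_{t+k})` is computed directly (not the FFT-based biased
#' estimator), which keeps small-sample values bounded and interpretable.
#'
#' @param x interval series or numeric vector.
#' @param max_lag largest lag (in ticks); series length must exceed
#'   `max_lag + 2`.
#' @return tibble with `lag` (0..`max_lag`) and `acf`; lag 0 is 1.
#' @export
interval_acf <- function(x, max_lag) {
  iv <- intervals_of(x)
  n <- length(iv)
  if (n <= max_lag + 2) abort("Series too short for `max_lag`.")
  if (sd(iv) == 0) abort("Zero-variance series; correlation undefined.")
  acf <- vapply(0:max_lag, function(k) {
    if (k == 0) 1 else cor(iv[1:(n - k)], iv[(1 + k):n])
  }, numeric(1))
  tibble(lag = 0:max_lag, acf = acf)
}

#' Dominant rhythm period from interval autocorrelation
#'
#' Finds the periodic structure the autocorrelation reveals: lags beyond
#' `min_lag` whose correlation exceeds the white-noise band
#' `band_factor / sqrt(n)` are grouped into contiguous runs; within the
#' first qualifying run of length >= 2 the lag of maximum correlation is
#' taken and converted to time via the mean interval. A run only
#' qualifies if it is preceded by at least one sub-band lag beyond
#' `min_lag`: for a periodic series the autocorrelation is (to first
#' order) a cosine in the lag, so the descending flank of its lag-0 peak
#' can itself exceed the band just past `min_lag` and must not be read as
#' a rhythm. Restricting to the first qualifying run also avoids the
#' ambiguity of a global argmax, which a periodic series shares across
#' all harmonic lags. With no qualifying run the result is "no rhythm"
#' (`rhythmic = FALSE`), not an error.
#'
#' @param x interval series or numeric vector.
#' @param min_lag smallest candidate lag (default 10).
#' @param max_lag largest candidate lag (default `min(600, floor(n / 2))`,
#'   keeping at least `n / 2` overlapping pairs at every candidate lag).
#' @param band_factor multiplier of the white-noise scale; the band at
#'   lag `k` is `band_factor / sqrt(n - k)`, reflecting the `n - k`
#'   overlapping pairs that enter the lag-`k` correlation (default 3).
#' @return one-row tibble with `lag`, `period_s`, `peak_corr`, `rhythmic`.
#' @export
dominant_period <- function(x, min_lag = 10, max_lag = NULL, band_factor = 3) {
  iv <- intervals_of(x)
  n <- length(iv)
  if (is.null(max_lag)) max_lag <- min(600L, floor(n / 2))
  ac <- interval_acf(iv, max_lag)
  cand <- ac[ac$lag > min_lag, ]
  band <- band_factor / sqrt(n - cand$lag)
  sig <- cand$acf > band
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  first <- which(runs$values & runs$lengths >= 2 & starts > 1)
  if (!length(first)) {
    return(tibble(lag = NA_integer_, period_s = NA_real_,
                  peak_corr = max(cand$acf), rhythmic = FALSE))
  }
  i0 <- starts[first[1]]
  i1 <- ends[first[1]]
  seg <- cand[i0:i1, ]
  best <- seg[which.max(seg$acf), ]
  tibble(lag = as.integer(best$lag), period_s = best$lag * mean(iv),
         peak_corr = best$acf, rhythmic = TRUE)
}
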