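#' Construct a frame sequence
#'
#' @param frames 3D array `[height, width, n_frames]` of 8-bit gray
#'   levels (0-255); at least two frames.
#' @param frame_rate frames per second.
#' @return object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3 || dim(frames)[3] < 2) {
    abort("`frames` must be a [h, w, n>=2] array.")
  }
  if (min(frames) < 0 || max(frames) > 255) {
    abort("Pixel values must lie in [0, 255].")
  }
  if (frame_rate <= 0) abort("`frame_rate` must be positive.")
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "frame_sequence")
}

#' Fraction of changed pixels between consecutive frames
#'
#' The "changed pixel" criterion is an absolute gray-level difference of
#' at least `pixel_delta_min` (a declared floor above sensor noise; the
#' frame-level percentages build on it).
#'
#' @param seq a [frame_sequence()].
#' @param pixel_delta_min per-pixel change threshold in gray levels
#'   (default 10).
#' @return tibble with one row per consecutive frame pair: `pair` (index,
#'   pair `i` compares frames `i` and `i+1`), `time_s` (time of the first
#'   frame of the pair) and `fraction` in `[0, 1]`.
#' @export
frame_change_fraction <- function(seq, pixel_delta_min = 10) {
  stopifnot(inherits(seq, "frame_sequence"))
  f <- seq$frames
  n <- dim(f)[3]
  npx <- prod(dim(f)[1:2])
  frac <- vapply(seq_len(n - 1), function(i) {
    sum(abs(f[, , i + 1] - f[, , i]) >= pixel_delta_min) / npx
  }, numeric(1))
  tibble(pair = seq_len(n - 1), time_s = (seq_len(n - 1) - 1) / seq$frame_rate,
         fraction = frac)
}

#' Binary motion from pixel-difference fractions
#'
#' A frame pair scores motion when its changed-pixel fraction *strictly
#' exceeds* `frame_fraction_threshold`. The default 0.085 (8.5%) is the
#' liberal threshold sitting above a typical 5.5% pixel-noise floor.
#'
#' @param seq a [frame_sequence()], or the output of
#'   [frame_change_fraction()].
#' @param frame_fraction_threshold fraction in `(0, 1)` (default 0.085).
#' @param pixel_delta_min per-pixel threshold, used when `seq` is a frame
#'   sequence.
#' @return tibble with `pair`, `time_s`, `fraction`, `motion` (0/1).
#' @export
pd_motion <- function(seq, frame_fraction_threshold = 0.085,
                      pixel_delta_min = 10) {
  if (frame_fraction_threshold < 0 || frame_fraction_threshold >= 1) {
    abort("`frame_fraction_threshold` must lie in [0, 1).")
  }
  fr <- if (inherits(seq, "frame_sequence")) {
    frame_change_fraction(seq, pixel_delta_min)
  } else {
    as_tibble(seq)
  }
  fr %>% mutate(motion = as.integer(.data$fraction > frame_fraction_threshold))
}

#' Two-stage binning of a binary motion series
#'
#' Reproduces the method-comparison pipeline: the frame-rate binary motion
#' series is first collapsed to `fine_bin`-second bins (a fine bin is 1 if
#' any of its frame pairs scored motion), then aggregated to
#' `coarse_bin`-second bins as the percent of fine bins with motion.
#'
#' @param motion output of [pd_motion()], or a tibble with `time_s` and
#'   `motion`.
#' @param fine_bin fine bin width in seconds (default 2).
#' @param coarse_bin coarse bin width in seconds (default 30); must be a
#'   multiple of `fine_bin`.
#' @param label method label carried on the result (default `"PD"`).
#' @return a method trace: tibble of class `method_trace` with
#'   `bin_start_s` and `percent` in `[0, 100]`.
#' @export
binarize_and_bin <- function(motion, fine_bin = 2, coarse_bin = 30,
                             label = "PD") {
  if (coarse_bin %% fine_bin != 0) {
    abort("`coarse_bin` must be a multiple of `fine_bin`.")
  }
  m <- as_tibble(motion)
  span <- max(m$time_s) # last pair start
  if (span < coarse_bin - fine_bin) {
    abort("Series shorter than one coarse bin.")
  }
  fine <- m %>%
    mutate(fine = floor(.data$time_s / fine_bin)) %>%
    group_by(.data$fine) %>%
    summarise(on = as.integer(any(.data$motion == 1)), .groups = "drop")
  per <- coarse_bin / fine_bin
  out <- fine %>%
    mutate(coarse = .data$fine %/% per) %>%
    group_by(.data$coarse) %>%
    summarise(percent = 100 * mean(.data$on), n_fine = n(), .groups = "drop") %>%
    filter(.data$n_fine == per) %>% # drop a trailing partial coarse bin
    mutate(bin_start_s = .data$coarse * coarse_bin) %>%
    dplyr::select("bin_start_s", "percent")
  method_trace(out$percent, bin = coarse_bin, label = label)
}

#' Build a method trace from per-bin percent values
#'
#' Used to ingest already-percent traces such as human-observer (OBS)
#' scores alongside detector (MDS) and pixel-difference (PD) traces.
#'
#' @param percent numeric vector of per-bin percent locomotion, in
#'   `[0, 100]`.
#' @param bin bin width in seconds (default 30).
#' @param label method label, e.g. `"OBS"`, `"MDS"`, `"PD"`.
#' @return tibble of class `method_trace` with `bin_start_s`, `percent`.
#' @export
method_trace <- function(percent, bin = 30, label = "method") {
  if (any(percent < 0 | percent > 100)) {
    abort("`percent` values must lie in [0, 100].")
  }
  out <- tibble(bin_start_s = (seq_along(percent) - 1) * bin,
                percent = as.numeric(percent))
  class(out) <- c("method_trace", class(out))
  attr(out, "label") <- label
  attr(out, "bin") <- bin
  out
}

#' Compare two motion-scoring methods
#'
#' @param a,b method traces on a common bin grid (tibbles with `percent`,
#'   or numeric vectors).
#' @return one-row tibble with `pearson_r` and `mean_diff_pct`, the
#'   relative difference of means `100 * (mean(a) - mean(b)) / mean(b)`.
#' @export
compare_methods <- function(a, b) {
  va <- if (is.data.frame(a)) a$percent else as.numeric(a)
  vb <- if (is.data.frame(b)) b$percent else as.numeric(b)
  if (length(va) != length(vb)) abort("Traces must share one bin grid.")
  if (sd(va) == 0 || sd(vb) == 0) {
    abort("Zero-variance trace: correlation undefined.")
  }
  tibble(pearson_r = cor(va, vb),
         mean_diff_pct = 100 * (mean(va) - mean(vb)) / mean(vb))
}

#' Generate synthetic grayscale video
#'
#' Static background plus independent per-pixel, per-frame noise toggles
#' calibrated so the expected changed-pixel fraction between consecutive
#' frames equals `noise_change_target`: each pixel is displaced by
#' `noise_delta` gray levels in a random subset of each frame (inclusion
#' probability `q` with `2q(1-q) = target`). An optional bright square
#' blob jumps to a random position in every frame of the scripted motion
#' epochs and sits at a fixed home position otherwise, emulating
#' locomotion bouts. Successive moving positions are constrained to be
#' disjoint (the blob travels at least its own side length between
#' frames), so every frame pair inside a motion epoch changes about twice
#' the blob area.
#'
#' @param duration_s video length in seconds.
#' @param frame_rate frames per second (default 10).
#' @param width,height frame size in pixels.
#' @param noise_change_target expected changed-pixel fraction from noise
#'   alone (default 0.055, a typical camera noise floor); 0 disables
#'   noise.
#' @param noise_delta gray-level excursion of noisy pixels (default 20,
#'   above the default per-pixel change threshold).
#' @param blob_size side length of the square blob in pixels; `NULL` for
#'   no blob.
#' @param script tibble with columns `start_s`, `end_s` of motion epochs
#'   (blob moves while `start_s <= t < end_s`).
#' @param background,blob_value gray levels of background and blob.
#' @param seed integer seed.
#' @return a [frame_sequence()].
#' @export
synth_video <- function(duration_s, frame_rate = 10, width = 40, height = 40,
                        noise_change_target = 0.055, noise_delta = 20,
                        blob_size = NULL, script = NULL,
                        background = 60, blob_value = 230, seed = 1) {
  if (noise_change_target < 0 || noise_change_target > 0.5) {
    abort("`noise_change_target` must lie in [0, 0.5].")
  }
  if (!is.null(blob_size) && (blob_size > width || blob_size > height)) {
    abort("Blob larger than the frame.")
  }
  if (!is.null(blob_size) && !is.null(script) &&
      height - blob_size < blob_size && width - blob_size < blob_size) {
    abort("Blob too large to move by its own size within the frame.")
  }
  set.seed(seed)
  n <- max(2, round(duration_s * frame_rate))
  q <- if (noise_change_target > 0) (1 - sqrt(1 - 2 * noise_change_target)) / 2
       else 0
  frames <- array(background, dim = c(height, width, n))
  moving <- rep(FALSE, n)
  if (!is.null(script) && nrow(script)) {
    t_frame <- (seq_len(n) - 1) / frame_rate
    for (r in seq_len(nrow(script))) {
      moving <- moving | (t_frame >= script$start_s[r] &
                          t_frame < script$end_s[r])
    }
  }
  home <- c(1, 1)
  pos <- home
  for (i in seq_len(n)) {
    fr <- matrix(background, height, width)
    if (q > 0) {
      mask <- matrix(runif(height * width) < q, height, width)
      fr[mask] <- background + noise_delta
    }
    if (!is.null(blob_size)) {
      if (moving[i]) {
        repeat {
          cand <- c(sample.int(height - blob_size + 1, 1),
                    sample.int(width - blob_size + 1, 1))
          if (max(abs(cand - pos)) >= blob_size) break
        }
        pos <- cand
      } else {
        pos <- home
      }
      fr[pos[1]:(pos[1] + blob_size - 1),
         pos[2]:(pos[2] + blob_size - 1)] <- blob_value
    }
    frames[, , i] <- fr
  }
  frame_sequence(frames, frame_rate)
}
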