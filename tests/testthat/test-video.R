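make_frames <- function(...) {
  mats <- list(...)
  array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
}

test_that("changed-pixel fraction counts pixels above the per-pixel floor", {
  f0 <- matrix(100, 10, 10)
  f1 <- f0; f1[1, 1] <- 120
  seq1 <- frame_sequence(make_frames(f0, f0, f1, 255 - f1), frame_rate = 5)
  fr <- frame_change_fraction(seq1, pixel_delta_min = 10)
  expect_equal(fr$fraction, c(0, 0.01, 1))
  # monotone non-increasing in the per-pixel threshold
  for (d in c(5, 15, 30)) {
    expect_lte(max(frame_change_fraction(seq1, d)$fraction -
                     frame_change_fraction(seq1, 5)$fraction), 0)
  }
  expect_error(frame_sequence(array(0, c(4, 4, 1)), 5), "n>=2")
  expect_error(frame_sequence(array(300, c(4, 4, 2)), 5), "0, 255")
})

test_that("motion thresholding is strict and respects the noise floor", {
  # noise calibrated to ~5.5% change sits below the 8.5% threshold
  v <- synth_video(60, frame_rate = 10, noise_change_target = 0.055, seed = 5)
  fr <- frame_change_fraction(v)
  expect_lt(abs(mean(fr$fraction) - 0.055), 0.005)
  expect_true(all(pd_motion(fr)$motion == 0))
  # a jumping blob covering ~10% of pixels exceeds it
  v2 <- synth_video(10, frame_rate = 10, noise_change_target = 0,
                    blob_size = 13, seed = 6,
                    script = tibble::tibble(start_s = 0, end_s = 10))
  expect_true(mean(pd_motion(v2)$motion) > 0.95)
  # threshold 0: any differing pixel scores motion
  m0 <- pd_motion(v, frame_fraction_threshold = 0)
  expect_true(all(m0$motion[fr$fraction > 0] == 1))
})

test_that("no noise and no blob means no change", {
  v <- synth_video(5, frame_rate = 10, noise_change_target = 0, seed = 1)
  expect_true(all(frame_change_fraction(v)$fraction == 0))
  expect_error(synth_video(5, blob_size = 100, seed = 1), "larger than")
})

test_that("two-stage binning reports percent of active fine bins", {
  motion <- tibble::tibble(time_s = seq(0, 59.9, by = 0.1),
                           motion = 0L)
  motion$motion[motion$time_s < 2] <- 1L       # 1 of 15 fine bins, bin 1
  motion$motion[motion$time_s >= 30] <- 1L     # all of bin 2
  tr <- binarize_and_bin(motion)
  expect_equal(tr$percent, c(100 / 15, 100))
  # re-binarizing a binary series changes nothing at the fine level
  motion2 <- motion
  motion2$motion <- as.integer(motion2$motion > 0)
  expect_identical(binarize_and_bin(motion2)$percent, tr$percent)
  expect_error(binarize_and_bin(motion, fine_bin = 2, coarse_bin = 7),
               "multiple")
  expect_error(binarize_and_bin(motion[1:20, ]), "shorter")
})

test_that("method comparison reproduces correlation and mean difference", {
  a <- method_trace(c(10, 20, 30), label = "MDS")
  expect_equal(as.data.frame(compare_methods(a, a)),
               data.frame(pearson_r = 1, mean_diff_pct = 0))
  cmp <- compare_methods(c(1, 2, 3), c(1, 2, 4))
  expect_equal(cmp$pearson_r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-9)
  b2 <- method_trace(c(20, 40, 60))
  cmp2 <- compare_methods(a, b2)
  expect_equal(cmp2$pearson_r, 1)
  expect_equal(cmp2$mean_diff_pct, -50)
  expect_error(compare_methods(a, method_trace(c(50, 50))), "grid")
  expect_error(compare_methods(c(1, 1), c(1, 2)), "Zero-variance")
})

test_that("the PD pipeline recovers a scripted locomotion profile end to end", {
  script <- tibble::tibble(start_s = c(0, 60, 90), end_s = c(30, 66, 120))
  v <- synth_video(120, frame_rate = 10, noise_change_target = 0.055,
                   blob_size = 13, script = script, seed = 6)
  tr <- binarize_and_bin(pd_motion(v), label = "PD")
  # per 30 s bin, percent of 2 s bins scripted as moving
  expected <- c(100, 0, 20, 100)
  quantum <- 100 / 15 # one fine bin
  expect_true(all(abs(tr$percent - expected) <= quantum + 1e-9))
  expect_equal(attr(tr, "label"), "PD")
})
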