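test_that("pulse extension merges retriggered events and keeps gaps", {
  expect_equal(as.data.frame(extend_pulses(0)),
               data.frame(high_start = 0, high_end = 1))
  expect_equal(as.data.frame(extend_pulses(c(0, 0.4, 0.9))),
               data.frame(high_start = 0, high_end = 1.9))
  expect_equal(as.data.frame(extend_pulses(c(0, 2.5))),
               data.frame(high_start = c(0, 2.5), high_end = c(1, 3.5)))
  expect_error(extend_pulses(c(2, 1)), "sorted")
})

test_that("total high time is bounded between hold and n * hold", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(1:40, 1)
    times <- sort(runif(n, 0, 20))
    hold <- runif(1, 0.2, 2)
    p <- extend_pulses(times, hold)
    high <- sum(p$high_end - p$high_start)
    expect_gte(high, hold - 1e-12)
    expect_lte(high, n * hold + 1e-12)
    expect_true(all(p$high_start[-1] >= p$high_end[-nrow(p)])) # disjoint
  }
})

test_that("well-separated events yield one record each on their own channel", {
  log <- log_events(cage_array(list("2" = c(1, 2, 3, 4, 5))), seed = 1,
                    dead_time = 0.1)
  expect_identical(nrow(log), 5L)
  expect_true(all(log$ch2 == 1L))
  expect_true(all(as.matrix(log[paste0("ch", c(1, 3:6))]) == 0L))
})

test_that("a shielded neighbor records nothing while the unshielded one picks up", {
  trace <- simulate_mouse(strain_profile("h", 0.5, 0.5, entrainment_rate = 0),
                          inverted_schedule(), seed = 2, duration_s = 1800)
  xt <- diag(6)
  xt[2, 1] <- 0.26
  xt[2, 3] <- 0.26 # nominal pickup, killed by the shield
  cages <- cage_array(list("2" = trace), crosstalk = xt,
                      shields = list(c(2, 3)))
  log <- log_events(cages, seed = 3)
  counts <- colSums(as.matrix(log[paste0("ch", 1:6)]))
  expect_equal(unname(counts[3]), 0)
  expect_gt(counts[1], 0)
  n <- counts[2]
  p <- 0.26
  expect_lt(abs(counts[1] / n - p), 3 * sqrt(p * (1 - p) / n) + 0.01)
  # never more records than physical + crosstalk events
  expect_lte(nrow(log), nrow(trace) * 2)
})

test_that("dead time coalesces bursts into one record with combined flags", {
  # cages 1 and 2 fire 10 ms apart; the second event falls in the dead time
  cages <- cage_array(list("1" = 5.00, "2" = 5.01))
  log <- log_events(cages, seed = 1, dead_time = 0.1)
  expect_identical(nrow(log), 1L)
  # the monostable of cage 2 is still low at the interrupt: its event came
  # after the record
  expect_identical(log$ch1, 1L)
  expect_identical(log$ch2, 0L)
  # reversed order: both within the hold window at the later interrupt
  cages2 <- cage_array(list("1" = c(5.00, 5.50)))
  log2 <- log_events(cages2, seed = 1, dead_time = 1)
  expect_identical(nrow(log2), 1L)
})

test_that("timestamps are floored to whole seconds", {
  log <- log_events(cage_array(list("1" = c(1.4, 3.9))), seed = 1)
  expect_identical(as.numeric(log$datetime) %% 60, c(1, 3))
})

test_that("the CSV log round-trips losslessly", {
  sch <- inverted_schedule()
  trace <- simulate_mouse(cd1_profile(), sch, days = 1, seed = 4)
  log <- log_events(cage_array(list("3" = trace)), seed = 5, schedule = sch)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(log, path)
  back <- read_event_log(path)
  expect_equal(back, log, ignore_attr = TRUE)
  expect_identical(readLines(path)[1], "datetime,ch1,ch2,ch3,ch4,ch5,ch6,light")
})

test_that("an empty log writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(cagewatch:::empty_event_log(), path)
  expect_identical(length(readLines(path)), 1L)
  expect_identical(nrow(read_event_log(path)), 0L)
})

test_that("reading rejects invalid rows and repairs ordering", {
  path <- withr::local_tempfile(fileext = ".csv")
  header <- "datetime,ch1,ch2,ch3,ch4,ch5,ch6,light"
  # flagless record violates the interrupt invariant
  writeLines(c(header, "2024-01-01 00:00:01,0,0,0,0,0,0,5"), path)
  expect_error(read_event_log(path), "no channel flag")
  # malformed field names its line
  writeLines(c(header, "2024-01-01 00:00:01,1,0,0,0,0,0,5",
               "not-a-date,1,0,0,0,0,0,5"), path)
  expect_error(read_event_log(path), "line 3")
  # non-monotone rows are re-sorted with a warning
  writeLines(c(header, "2024-01-01 00:00:02,1,0,0,0,0,0,5",
               "2024-01-01 00:00:01,0,1,0,0,0,0,5"), path)
  expect_warning(log <- read_event_log(path), "re-sorted")
  expect_identical(log$ch2, c(1L, 0L))
})

test_that("per-minute activity counts conserve records and zero-fill gaps", {
  log <- log_events(cage_array(list("1" = c(10, 20, 30, 200))), seed = 1)
  apm <- activity_per_minute(log, 1)
  expect_identical(sum(apm$count), 4L)
  expect_identical(apm$count[1], 3L)
  expect_true(any(apm$count == 0L))
  span <- as.POSIXct(c("2024-01-01 00:00:00", "2024-01-01 00:05:00"),
                     tz = "UTC")
  empty <- activity_per_minute(tiny_log(1), 2, span = span)
  expect_identical(empty$count, rep(0L, 5))
  expect_error(activity_per_minute(log, 9), "Unknown channel")
})
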