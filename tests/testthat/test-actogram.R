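test_that("binning is half-open, day-aligned and conserves counts", {
  b <- bin_activity(grid_trace(c(10 * 60, 20 * 60, 65 * 60)))
  expect_equal(b$count[1:3], c(2L, 1L, 0L))
  expect_identical(sum(b$count), 3L)
  expect_identical(nrow(b), 24L)
  empty <- bin_activity(grid_trace(numeric(0)), days = 1)
  expect_true(all(empty$count == 0L))
  expect_error(bin_activity(grid_trace(1), bin_width_s = 5000),
               "divide 24 h")
})

test_that("binning an event log agrees with binning its source trace", {
  tr <- simulate_mouse(cd1_profile(), inverted_schedule(), days = 1, seed = 11)
  log <- log_events(cage_array(list("1" = tr)), seed = 12, dead_time = 0.001)
  b_log <- bin_activity(log, channel = 1, days = 1)
  b_tr <- bin_activity(tr, days = 1)
  # dead time of 1 ms loses essentially nothing at these rates
  expect_equal(sum(b_log$count), nrow(log))
  expect_lt(sum(abs(b_log$count - b_tr$count)) / sum(b_tr$count), 0.01)
})

test_that("group actogram averages elementwise with SEM across animals", {
  b1 <- bin_activity(grid_trace(c(100, 200), id = "a"), days = 1)
  b2 <- bin_activity(grid_trace(numeric(0), id = "b"), days = 1)
  g <- group_actogram(list(b1, b2))
  expect_equal(g$mean[1], 1) # counts {2, 0} -> mean 1
  expect_equal(g$sem[1], 1)  # sd sqrt(2) / sqrt(2)
  expect_identical(unique(g$n_animals), 2L)
  # identical members have zero SEM
  g2 <- group_actogram(list(b1, dplyr::mutate(b1, animal_id = "c")))
  expect_true(all(g2$sem == 0))
  expect_warning(group_actogram(b1), "Single animal")
  b3 <- bin_activity(grid_trace(100, id = "d"), bin_width_s = 1800, days = 1)
  expect_error(group_actogram(list(b1, b3)), "identical bin grid")
})

test_that("group SEM shrinks like 1/sqrt(n) for iid animals", {
  sch <- inverted_schedule()
  mk <- function(n, s0) {
    lapply(seq_len(n), function(i) {
      bin_activity(simulate_mouse(cd1_profile(), sch, days = 1,
                                  seed = s0 + i,
                                  animal_id = paste0("m", s0 + i)),
                   days = 1)
    })
  }
  g4 <- group_actogram(mk(4, 0))
  g16 <- group_actogram(mk(16, 100))
  active <- g4$mean > 100 # compare SEM where counts are substantial
  ratio <- median(g16$sem[active] / g4$sem[active])
  expect_lt(abs(ratio - 0.5), 0.25)
})

test_that("daily totals and windows partition the day", {
  uniform <- grid_trace(seq(0.5, 2 * 86400 - 0.5, by = 360)) # 10/h, 2 days
  b <- bin_activity(uniform, days = 2)
  d <- daily_totals(b)
  expect_equal(d$total, c(240L, 240L))
  w <- window_activity(b, c(14, 20))
  expect_equal(w$count, c(60L, 60L))
  wa <- window_activity(b, c(2, 8))
  wb <- window_activity(b, c(8, 14))
  wc <- window_activity(b, c(14, 20))
  wrest <- dplyr::bind_rows(window_activity(b, c(0, 2)),
                            window_activity(b, c(20, 24))) |>
    dplyr::group_by(animal_id, day) |> dplyr::summarise(count = sum(count),
                                                        .groups = "drop")
  expect_equal(wa$count + wb$count + wc$count + wrest$count, d$total)
  expect_error(window_activity(b, c(1.5, 7.5)), "aligned")
  expect_error(window_activity(b, c(20, 26)), "within one day")
})

test_that("hyperactive animals double the daily totals of controls", {
  sch <- shifted_schedule()
  t_cd1 <- simulate_mouse(cd1_profile(), sch, days = 3, seed = 21)
  t_lab <- simulate_mouse(lab_profile(), sch, days = 3, seed = 22)
  r <- sum(daily_totals(bin_activity(t_lab, days = 3))$total) /
    sum(daily_totals(bin_activity(t_cd1, days = 3))$total)
  expect_lt(abs(r - 2), 0.2)
})

test_that("modulation is 100% for stationary activity and tracks rate steps", {
  sch <- inverted_schedule()
  # deterministic uniform grid: every transition sees equal pre/post counts
  m <- light_modulation(grid_trace(seq(0.5, 86400, by = 10)), sch)
  expect_true(all(m$modulation_pct == 100))
  # rate doubling exactly at the dark onset (8 AM = 28800 s)
  ev <- c(seq(28800 - 3 * 3600, 28800, by = 10)[-1] - 5,
          seq(28800, 28800 + 3 * 3600, by = 5)[-1] - 2.5)
  m2 <- light_modulation(ev, sch, span_s = c(0, 86400))
  dark_on <- m2[m2$to_state == "dark", ]
  expect_equal(dark_on$modulation_pct, 200)
  # zero pre-window yields an undefined entry, not a division
  m3 <- light_modulation(c(28900, 28950), sch, span_s = c(0, 86400))
  expect_true(is.na(m3$modulation_pct[m3$to_state == "light"]))
})

test_that("non-entraining animals show no modulation at post-shift dark onsets", {
  sch <- shifted_schedule()
  mods <- sapply(1:5, function(s) {
    tr <- simulate_mouse(lab_profile(), sch, days = 6, seed = 30 + s)
    m <- light_modulation(tr, sch, span_s = c(0, 6 * 86400))
    # dark onsets on post-shift days 4-6 land at 2 AM
    post <- m$to_state == "dark" & m$time_h > 3 * 24
    median(m$modulation_pct[post], na.rm = TRUE)
  })
  expect_true(all(mods > 80 & mods < 125))
})

test_that("phase-shift estimation matches the rotation oracle on all 24 shifts", {
  set.seed(8)
  profile <- rpois(24, lambda = c(rep(40, 12), rep(4, 12)))
  for (k in 0:23) {
    rotated <- profile[((seq_len(24) - 1 - k) %% 24) + 1] # delay by k bins
    est <- estimate_phase_shift(profile, rotated)
    expect_equal(est$shift_h, cagewatch:::wrap_half_day(k))
  }
  expect_equal(estimate_phase_shift(profile, profile)$shift_h, 0)
  expect_error(estimate_phase_shift(rep(1, 24), profile), "Flat")
})

test_that("entraining simulations recover the -6 h schedule advance", {
  sch <- shifted_schedule()
  shifts <- sapply(1:20, function(s) {
    b <- bin_activity(simulate_mouse(cd1_profile(), sch, days = 6, seed = s),
                      days = 6)
    estimate_phase_shift(daily_profile(b, 1:2), daily_profile(b, 5:6))$shift_h
  })
  expect_gte(mean(shifts == -6), 0.9)
})

test_that("post-shift light-phase activity of entrained animals declines", {
  sch <- shifted_schedule()
  tr <- simulate_mouse(cd1_profile(), sch, days = 6, seed = 77)
  wc <- window_activity(bin_activity(tr, days = 6), c(14, 20))
  # window C (2 PM - 8 PM) is dark pre-shift, light after entrainment
  expect_lt(mean(wc$count[wc$day %in% 5:6]), 0.4 * mean(wc$count[wc$day %in% 1:2]))
})
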