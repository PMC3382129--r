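test_that("constant traces normalize to identically zero percent", {
  ts <- time_series(rep(120, 600), fs_hz = 10, unit = "doppler_au")
  out <- normalize_rcbf(ts, c(0, 30), allow_short_baseline = TRUE)
  expect_true(all(out$values == 0))
  expect_equal(out$unit, "percent")
  expect_equal(attr(out, "baseline_mean_au"), 120)
})

test_that("a step from 100 to 220 a.u. reads as a +120% plateau", {
  dop <- make_doppler_trace(duration_s = 120, fs_hz = 10, baseline_au = 100,
                            step_pct = 120, step_at_s = 60)
  out <- normalize_rcbf(dop$series, c(0, 60), allow_short_baseline = TRUE)
  tms <- sample_times(out)
  expect_equal(unique(out$values[tms >= 60]), 120)
  expect_equal(unique(out$values[tms < 60]), 0)
})

test_that("programmed steps are recovered within noise over several levels", {
  for (k in c(-50, 50, 100)) {
    dop <- make_doppler_trace(duration_s = 240, fs_hz = 10, baseline_au = 200,
                              step_pct = k, step_at_s = 120, noise_sd = 5,
                              seed = 40 + k)
    out <- normalize_rcbf(dop$series, c(0, 120), allow_short_baseline = TRUE)
    plateau <- out$values[sample_times(out) >= 130]
    se <- 100 * (5 / 200) / sqrt(length(plateau))
    expect_lt(abs(mean(plateau) - k), 4 * se + 0.05)
  }
})

test_that("normalization is invariant to positive rescaling of raw units", {
  dop <- make_doppler_trace(noise_sd = 3, seed = 8)
  a <- normalize_rcbf(dop$series, c(0, 60), allow_short_baseline = TRUE)
  scaled <- time_series(dop$series$values * 13.7, dop$series$fs_hz, "doppler_au")
  b <- normalize_rcbf(scaled, c(0, 60), allow_short_baseline = TRUE)
  expect_equal(a$values, b$values, tolerance = 1e-9)
})

test_that("short baselines and non-positive baselines are rejected", {
  ts <- time_series(rep(100, 1200), 10, "doppler_au")
  expect_error(normalize_rcbf(ts, c(0, 60)), "15 min")
  neg <- time_series(c(rep(-5, 300), rep(10, 300)), 10, "doppler_au")
  expect_error(normalize_rcbf(neg, c(0, 30), allow_short_baseline = TRUE),
               "non-positive")
})

test_that("epoch averages match brute-force slice means", {
  p <- stim_protocol(n_trains = 3, sets_per_train = 2, set_duration_s = 10,
                     inter_set_gap_s = 5, off_time_s = 30)
  sch <- expand_schedule(p)
  set.seed(17)
  vals <- rnorm(2000)
  tr <- time_series(vals, fs_hz = 10, unit = "percent")
  ep <- epoch_average(tr, sch, window_s = 8)
  tms <- sample_times(tr)
  for (i in seq_len(nrow(sch))) {
    expect_equal(ep$on_mean_pct[i],
                 mean(vals[tms >= sch$on_start_s[i] & tms < sch$on_end_s[i]]))
    expect_equal(ep$post_mean_pct[i],
                 mean(vals[tms >= sch$on_end_s[i] & tms < sch$on_end_s[i] + 8]))
  }
})

test_that("epochs outside the trace are marked missing and ON/OFF separate", {
  p <- stim_protocol(n_trains = 2, sets_per_train = 1, set_duration_s = 10,
                     off_time_s = 1000)
  sch <- expand_schedule(p)
  tms <- (0:499) / 10
  on1 <- tms >= sch$on_start_s[1] & tms < sch$on_end_s[1]
  tr <- time_series(ifelse(on1, 100, 0), 10, "percent")
  ep <- epoch_average(tr, sch, window_s = 10)
  expect_equal(ep$on_mean_pct[1], 100)
  expect_equal(ep$post_mean_pct[1], 0)
  expect_true(is.na(ep$on_mean_pct[2]))  # second train beyond the recording
})
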