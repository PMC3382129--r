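test_that("zero-phase band-pass passes in-band tones without lag", {
  fs <- 1000
  tone <- time_series(sin(2 * pi * 10 * (0:9999) / fs), fs, "ecog_uv")
  out <- bandpass_zero_phase(tone, 2, 90)
  gain <- sd(out$values) / sd(tone$values)
  expect_gte(gain, 0.95); expect_lte(gain, 1.0)
  cc <- ccf(out$values, tone$values, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("out-of-band components are strongly attenuated", {
  fs <- 1000
  slow <- time_series(sin(2 * pi * 0.5 * (0:19999) / fs), fs, "ecog_uv")
  out <- bandpass_zero_phase(slow, 2, 90)
  expect_lt(sd(out$values) / sd(slow$values), 0.1)
  zero <- time_series(rep(0, 5000), fs, "ecog_uv")
  expect_true(all(abs(bandpass_zero_phase(zero)$values) < 1e-12))
  expect_error(bandpass_zero_phase(slow, 2, 600), "Nyquist")
})

test_that("a pure 8 Hz tone concentrates its power in the 5-10 Hz band", {
  tone <- time_series(50 * sin(2 * pi * 8 * (0:59999) / 1000), 1000, "ecog_uv")
  bp <- band_powers(tone, normalization = "per_session")
  expect_gte(bp$power[["5-10"]], 0.95)
  expect_equal(sum(bp$power), 1, tolerance = 1e-12)
})

test_that("band power tracks time-domain variance (Parseval)", {
  rec <- make_ecog(ecog_spec(duration_s = 120), seed = 31)
  filt <- bandpass_zero_phase(rec$series)
  tot <- band_powers(filt, bands = list(all = c(2, 90)),
                     normalization = "none")$power[["all"]]
  expect_lt(abs(tot - var(filt$values)) / var(filt$values), 0.05)
})

test_that("day-1 normalization returns fold changes and demands a reference", {
  day1 <- bandpass_zero_phase(make_ecog(ecog_spec(duration_s = 60), seed = 41)$series)
  day4 <- time_series(day1$values * 2, day1$fs_hz, "ecog_uv")
  ref <- band_powers(day1, normalization = "none")
  fold <- band_powers(day4, normalization = "to_day1", day1 = ref)
  expect_equal(unname(fold$power), rep(4, 5), tolerance = 1e-9)
  expect_error(band_powers(day4, normalization = "to_day1"), "day-1")
})

test_that("injected seizure-like events are recovered with accurate onsets", {
  onsets <- c(20, 50, 80)
  ev <- data.frame(onset_s = onsets, duration_s = 3, amplitude_multiple = 5,
                   carrier_hz = 80)
  rec <- make_ecog(ecog_spec(duration_s = 110, events = ev), seed = 51)
  day1 <- make_ecog(ecog_spec(duration_s = 90), seed = 52)
  det <- detect_seizure_like_events(rec$series, day1$series)
  expect_equal(nrow(det$events), 3)
  expect_lt(max(abs(det$events$onset_s - onsets)), 0.5)
  # burden conservation: sec/h x hours == total event seconds
  expect_equal(det$fast_activity_sec_per_h * det$recording_length_s / 3600,
               sum(det$events$duration_s))
})

test_that("event-free background yields no events", {
  bg <- make_ecog(ecog_spec(duration_s = 300), seed = 61)
  day1 <- make_ecog(ecog_spec(duration_s = 90), seed = 62)
  det <- detect_seizure_like_events(bg$series, day1$series)
  expect_equal(nrow(det$events), 0)
  expect_equal(det$fast_activity_sec_per_h, 0)
})

test_that("event detection is amplitude-scale equivariant", {
  ev <- data.frame(onset_s = 15, duration_s = 3, amplitude_multiple = 5,
                   carrier_hz = 80)
  rec <- make_ecog(ecog_spec(duration_s = 60, events = ev), seed = 71)
  day1 <- make_ecog(ecog_spec(duration_s = 70), seed = 72)
  d1 <- detect_seizure_like_events(rec$series, day1$series)
  scale_ts <- function(x, k) time_series(x$values * k, x$fs_hz, x$unit)
  d2 <- detect_seizure_like_events(scale_ts(rec$series, 7.3),
                                   scale_ts(day1$series, 7.3))
  expect_equal(d1$events, d2$events)
})

test_that("events close together merge; sampling-rate mismatch errors", {
  ev <- data.frame(onset_s = c(20, 23.2), duration_s = 3,
                   amplitude_multiple = 5, carrier_hz = 80)
  rec <- make_ecog(ecog_spec(duration_s = 60, events = ev), seed = 81)
  day1 <- make_ecog(ecog_spec(duration_s = 70), seed = 82)
  det <- detect_seizure_like_events(rec$series, day1$series, merge_gap_s = 0.5)
  expect_equal(nrow(det$events), 1)  # 0.2 s gap < merge_gap
  wrong_fs <- time_series(day1$series$values, 500, "ecog_uv")
  expect_error(detect_seizure_like_events(rec$series, wrong_fs), "mismatch")
  short <- time_series(rnorm(1000), 1000, "ecog_uv")
  expect_error(detect_seizure_like_events(rec$series, short), "60 s")
})
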