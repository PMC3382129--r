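test_that("noiseless ridge rasterizes to the programmed width", {
  vs <- ridge_fixture("horizontal", diameter_um = 20)
  fr <- get_frame(vs$stack, 1)
  # every column crossing the vessel has a foreground run of exactly 20 px
  runs <- apply(fr[, 10:50], 2, function(col) sum(col > 0.2 + 0.3))
  expect_true(all(runs == 20))
  expect_equal(unique(vs$truth$diam_um), 20)
})

test_that("programmed dilation shows up in the truth table by construction", {
  dil <- function(s_um, t_s) rep(20 * (1 + 0.12 * (t_s >= 10)), length(s_um))
  vs <- ridge_fixture("horizontal", diameter_fun = dil, n_frames = 10)
  tt <- vs$truth
  expect_equal(max(tt$diam_um) / min(tt$diam_um), 1.12)
})

test_that("generators are deterministic given (spec, seed)", {
  a <- ridge_fixture("diagonal", noise_sd = 0.1, seed = 7)
  b <- ridge_fixture("diagonal", noise_sd = 0.1, seed = 7)
  expect_identical(a$stack$frames, b$stack$frames)
  c_ <- ridge_fixture("diagonal", noise_sd = 0.1, seed = 8)
  expect_false(identical(a$stack$frames, c_$stack$frames))

  e1 <- make_ecog(ecog_spec(duration_s = 10), seed = 5)
  e2 <- make_ecog(ecog_spec(duration_s = 10), seed = 5)
  expect_identical(e1$series$values, e2$series$values)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(ridge_fixture("horizontal", noise_sd = 0.05, seed = 9))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("vessel wider than the image is rejected", {
  spec <- vessel_spec(rbind(c(15.5, 2), c(15.5, 29)), diameter_um = 80)
  expect_error(make_vessel_stack(spec, list(H = 32, W = 32, pixel_size_um = 1,
                                            n_frames = 1, frame_interval_s = 2),
                                 seed = 1), "wider")
})

test_that("angiography truth records programmed transit and slope", {
  ang <- angio_fixture(arterial = bolus_spec(1, 1, 110, baseline_iu = 10),
                       venous = bolus_spec(2.5, 1, 80, baseline_iu = 10))
  expect_equal(ang$truth$p2p$p2p_interval_s, 1.5)
  expect_equal(ang$truth$per_roi$slope_iu_per_s[1], 100)
  # zero noise linear ramp 10 -> 110 iu over 2 s programs slope 50 iu/s
  ang2 <- angio_fixture(arterial = bolus_spec(1, 2, 110, baseline_iu = 10))
  expect_equal(ang2$truth$per_roi$slope_iu_per_s[1], 50)
})

test_that("overlapping angiography ROIs are rejected", {
  r1 <- roi("artery", mask = rect_mask(16, 16, 3:8, 3:8))
  r2 <- roi("vein", mask = rect_mask(16, 16, 6:12, 6:12))
  expect_error(make_angio_stack(list(A = list(roi = r1, spec = bolus_spec(1, 1, 50)),
                                     V = list(roi = r2, spec = bolus_spec(2, 1, 40))),
                                list(H = 16, W = 16, pixel_size_um = 1, fs = 30,
                                     duration_s = 5), seed = 1),
               "disjoint")
})

test_that("noisy ROI means scatter around the programmed curve (Monte Carlo)", {
  sp <- bolus_spec(1, 1.5, 60, baseline_iu = 10)
  geom <- list(H = 12, W = 12, pixel_size_um = 1, fs = 30, duration_s = 4)
  r1 <- roi("artery", mask = rect_mask(12, 12, 4:9, 4:9))
  frame_idx <- 45  # mid-rise
  t <- (frame_idx - 1) / 30
  programmed <- 10 + (60 - 10) * (t - 1) / 1.5
  reps <- vapply(1:100, function(s) {
    a <- make_angio_stack(list(A = list(roi = r1, spec = sp)), geom,
                          seed = s, noise_sd = 4)
    mean(get_frame(a$stack, frame_idx)[r1$mask])
  }, 0)
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - programmed), 3 * se + 1e-9)
})

test_that("ECoG background hits the programmed RMS and events the truth list", {
  bg <- make_ecog(ecog_spec(duration_s = 60, rms_uv = 50), seed = 2)
  expect_equal(nrow(bg$truth), 0)
  expect_lt(abs(sd(bg$series$values) - 50) / 50, 0.05)

  ev <- data.frame(onset_s = 10, duration_s = 4, amplitude_multiple = 5,
                   carrier_hz = 80)
  rec <- make_ecog(ecog_spec(duration_s = 30, events = ev), seed = 3)
  expect_equal(rec$truth$duration_s, 4)
  expect_equal(rec$truth$onset_s, 10)
  # the burst actually raises local amplitude around its onset
  seg <- rec$series$values[(10 * 1000):(14 * 1000)]
  expect_gt(max(abs(seg)), 4 * 50)
})

test_that("events outside the recording are rejected", {
  ev <- data.frame(onset_s = 58, duration_s = 4, amplitude_multiple = 5,
                   carrier_hz = 80)
  expect_error(ecog_spec(duration_s = 60, events = ev))
})

test_that("Evans-blue image programs an exact blob fraction and level", {
  eb <- make_evansblue_image(0.25, blob_blue = 180, background_blue = 60)
  blue <- eb$img[, , 3]
  expect_equal(mean(blue[eb$treated_mask] > 120), 0.25)
  expect_equal(unique(blue[eb$treated_mask & blue > 120]), 180)
  expect_equal(eb$truth$fraction, 0.25)
  # fraction 0: hemispheres identical in the blue channel
  eb0 <- make_evansblue_image(0, blob_blue = 180)
  expect_equal(sort(eb0$img[, , 3][eb0$treated_mask]),
               sort(eb0$img[, , 3][eb0$control_mask]))
})

test_that("coronal sections program per-section and aggregate loss", {
  cs <- make_coronal_sections(n_sections = 6, loss_fraction = 0.371)
  expect_length(cs$sections, 6)
  expect_equal(attr(cs$truth, "aggregate_pct_loss"), 37.1, tolerance = 0.05)
  cs0 <- make_coronal_sections(n_sections = 3, loss_fraction = 0)
  expect_true(all(cs0$truth$ipsi_px == cs0$truth$contra_px))
})
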