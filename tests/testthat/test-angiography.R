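test_that("ROI curves recover the programmed peak time within one frame", {
  ang <- angio_fixture(arterial = bolus_spec(1, 1, 110, baseline_iu = 10))
  ra <- roi("artery", mask = rect_mask(32, 32, 5:10, 5:10))
  tr <- roi_intensity_curve(ang$stack, ra)
  expect_lt(abs(tr$peak_time_s - 2.0), 1 / 30 + 1e-9)
  expect_false(tr$no_bolus)
  expect_equal(tr$baseline_iu, 10, tolerance = 1e-6)
})

test_that("a constant stack is flagged as having no bolus", {
  st <- image_stack(array(7, c(20, 16, 16)), 1, 1 / 30)
  r <- roi("artery", mask = rect_mask(16, 16, 4:8, 4:8))
  expect_warning(tr <- roi_intensity_curve(st, r), "no bolus")
  expect_true(tr$no_bolus)
  expect_equal(tr$peak_iu, tr$baseline_iu)
  expect_error(peak_to_peak(tr, tr), "no peak")
  expect_error(slope_to_max(tr), "no rise")
})

test_that("a one-pixel ROI reproduces that pixel's time course", {
  ang <- angio_fixture()
  m <- matrix(FALSE, 32, 32); m[7, 7] <- TRUE
  tr <- roi_intensity_curve(ang$stack, roi("artery", mask = m))
  expect_equal(tr$series$values, ang$stack$frames[, 7, 7])
})

test_that("peak-to-peak interval recovers programmed transit within one frame", {
  ang <- angio_fixture(arterial = bolus_spec(1, 1, 110, baseline_iu = 10),
                       venous = bolus_spec(2.5, 1, 80, baseline_iu = 10))
  ta <- roi_intensity_curve(ang$stack, roi("artery", mask = rect_mask(32, 32, 5:10, 5:10)))
  tv <- roi_intensity_curve(ang$stack, roi("vein", mask = rect_mask(32, 32, 20:25, 20:25)))
  expect_lt(abs(peak_to_peak(ta, tv) - ang$truth$p2p$p2p_interval_s),
            1 / 30 + 1e-9)
  expect_equal(peak_to_peak(ta, ta), 0)
  expect_warning(p <- peak_to_peak(tv, ta), "precedes")
  expect_lt(p, 0)
})

test_that("slope to max matches the closed-form ramp and is linear in amplitude", {
  # ramp 10 -> 110 iu over 2 s: mean rise slope 50 iu/s
  ang <- angio_fixture(arterial = bolus_spec(1, 2, 110, baseline_iu = 10),
                       duration_s = 15)
  ta <- roi_intensity_curve(ang$stack, roi("artery", mask = rect_mask(32, 32, 5:10, 5:10)))
  s1 <- slope_to_max(ta)
  expect_lt(abs(s1 - 50) / 50, 0.05)
  # doubling the excursion with the same rise time doubles the slope
  ang2 <- angio_fixture(arterial = bolus_spec(1, 2, 210, baseline_iu = 10),
                        duration_s = 15)
  ta2 <- roi_intensity_curve(ang2$stack, roi("artery", mask = rect_mask(32, 32, 5:10, 5:10)))
  expect_equal(slope_to_max(ta2) / s1, 2, tolerance = 0.02)
})

test_that("transit metrics are invariant to intensity offset and time shift", {
  ang <- angio_fixture()
  ra <- roi("artery", mask = rect_mask(32, 32, 5:10, 5:10))
  rv <- roi("vein", mask = rect_mask(32, 32, 20:25, 20:25))
  base <- transit_metrics(roi_intensity_curve(ang$stack, ra),
                          roi_intensity_curve(ang$stack, rv))
  shifted <- image_stack(ang$stack$frames + 50, ang$stack$pixel_size_um,
                         ang$stack$frame_interval_s)
  off <- transit_metrics(roi_intensity_curve(shifted, ra),
                         roi_intensity_curve(shifted, rv))
  expect_equal(off$p2p_interval_s, base$p2p_interval_s)
  expect_equal(off$slope_to_max_iu_per_s, base$slope_to_max_iu_per_s,
               tolerance = 1e-9)

  later <- image_stack(ang$stack$frames, ang$stack$pixel_size_um,
                       ang$stack$frame_interval_s, t0_s = 30)
  ta_l <- roi_intensity_curve(later, ra)
  expect_equal(ta_l$peak_time_s,
               roi_intensity_curve(ang$stack, ra)$peak_time_s + 30)
  tshift <- transit_metrics(ta_l, roi_intensity_curve(later, rv))
  expect_equal(tshift$p2p_interval_s, base$p2p_interval_s)
})

test_that("p2p estimates decrease strictly across a programmed flow series", {
  delays <- c(2.0, 1.6, 1.2, 0.8, 0.5)  # increasing flow, shrinking transit
  est <- vapply(seq_along(delays), function(i) {
    ang <- angio_fixture(arterial = bolus_spec(1, 1, 110, baseline_iu = 10),
                         venous = bolus_spec(1 + delays[i], 1, 80, baseline_iu = 10),
                         duration_s = 10)
    ta <- roi_intensity_curve(ang$stack, roi("artery", mask = rect_mask(32, 32, 5:10, 5:10)))
    tv <- roi_intensity_curve(ang$stack, roi("vein", mask = rect_mask(32, 32, 20:25, 20:25)))
    peak_to_peak(ta, tv)
  }, 0)
  expect_true(all(diff(est) < 0))
})

test_that("empty ROI against a stack errors", {
  ang <- angio_fixture()
  expect_error(roi_intensity_curve(ang$stack,
                                   roi("artery", mask = rect_mask(8, 8, 2:3, 2:3))),
               "match")
})
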