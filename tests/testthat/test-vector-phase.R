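test_that("CBV/COE rotation: worked values and isometry", {
  expect_equal(to_cbv_coe(0, 0), list(cbv = 0, coe = 0))
  expect_equal(to_cbv_coe(1, 1), list(cbv = sqrt(2), coe = 0))
  expect_equal(to_cbv_coe(1, 0), list(cbv = 1 / sqrt(2), coe = -1 / sqrt(2)))
  set.seed(10)
  hbo <- rnorm(1e4); hbr <- rnorm(1e4)
  rot <- to_cbv_coe(hbo, hbr)
  expect_equal(rot$cbv^2 + rot$coe^2, hbo^2 + hbr^2, tolerance = 1e-12)
})

test_that("magnitude and full-quadrant angle, with the rotation identity", {
  mp <- magnitude_phase(3, 4)
  expect_equal(mp$magnitude, 5)
  expect_equal(magnitude_phase(1, 1)$angle_deg, 45)
  expect_true(is.na(magnitude_phase(0, 0)$angle_deg))
  mp2 <- magnitude_phase(2, 1)
  expect_equal(mp2$angle_deg, atan(1 / 2) * 180 / pi, tolerance = 1e-12)
  rot <- to_cbv_coe(2, 1)
  expect_equal(atan(rot$coe / rot$cbv) * 180 / pi + 45, mp2$angle_deg,
               tolerance = 1e-12)
  # identity holds mod 360 for CBV > 0 and mod 180 wherever CBV != 0
  set.seed(11)
  hbo <- rnorm(500); hbr <- rnorm(500)
  rot <- to_cbv_coe(hbo, hbr)
  keep <- abs(rot$cbv) > 1e-6
  lhs <- magnitude_phase(hbo, hbr)$angle_deg[keep]
  rhs <- atan(rot$coe[keep] / rot$cbv[keep]) * 180 / pi + 45
  d <- lhs - rhs
  expect_lt(max(abs(d - 180 * round(d / 180))), 1e-9)
  dpos <- d[rot$cbv[keep] > 0]
  expect_lt(max(abs(dpos - 360 * round(dpos / 360))), 1e-9)
})

test_that("phase classification matches hand-checked points", {
  expect_equal(classify_phase(2, 1), 1L)
  expect_equal(classify_phase(-1, 0.5), 4L)
  expect_equal(classify_phase(-1, -2), 6L)
  expect_equal(classify_phase(-0.2, 0.9), 3L)
  expect_equal(classify_phase(0.5, 1.2), 2L)
  expect_equal(classify_phase(-0.9, -0.5), 5L)
  expect_equal(classify_phase(0.9, -0.5), 8L)
  expect_equal(classify_phase(0.5, -0.9), 7L)
  # boundaries and origin classify as none
  expect_true(is.na(classify_phase(0, 0)))
  expect_true(is.na(classify_phase(1, 1)))
  expect_true(is.na(classify_phase(1, 0)))
  expect_true(is.na(classify_phase(0, -1)))
})

test_that("off-boundary points satisfy exactly one phase predicate", {
  set.seed(12)
  hbo <- rnorm(1e4); hbr <- rnorm(1e4)
  rot <- to_cbv_coe(hbo, hbr)
  on_boundary <- hbo == 0 | hbr == 0 | hbo == hbr | rot$cbv == 0 |
    rot$coe == 0 | rot$cbv == rot$coe
  ph <- classify_phase(hbo, hbr)
  expect_true(all(!is.na(ph[!on_boundary])))
  # mutual exclusivity: brute-force count of satisfied predicate sets
  cbv <- rot$cbv; coe <- rot$coe
  preds <- cbind(
    0 < hbr & hbr < hbo & coe < 0 & 0 < cbv,
    0 < hbo & hbo < hbr & 0 < coe & coe < cbv,
    hbo < 0 & 0 < hbr & 0 < cbv & cbv < coe,
    hbo < 0 & 0 < hbr & cbv < 0 & 0 < coe,
    hbo < hbr & hbr < 0 & cbv < 0 & 0 < coe,
    hbr < hbo & hbo < 0 & cbv < coe & coe < 0,
    hbr < 0 & 0 < hbo & coe < cbv & cbv < 0,
    hbr < 0 & 0 < hbo & coe < 0 & 0 < cbv)
  counts <- rowSums(preds)
  expect_true(all(counts[!on_boundary] == 1))
  expect_equal(ph[!on_boundary],
               apply(preds[!on_boundary, ], 1, which))
})

test_that("most active channel maximizes trial-vs-rest HbO contrast", {
  # 3-channel toy, gains (0.5, 2, 1), no noise
  fs <- 10
  stim <- stimulus_boxcar(fs, 10, 20, 1, lead_rest_s = 10)
  h <- canonical_hrf(hrf_params(), 20, fs)
  u <- desired_hrf(h, stim)$u
  gains <- c(0.5, 2, 1)
  hbo <- sapply(gains, function(g) g * u)
  hbr <- -0.3 * hbo
  rec <- make_record(hbo, hbr, fs = fs, rest_n = 100)
  expect_equal(select_most_active_channel(rec), 2)
  # tie-break to the lowest id among identical channels
  hbo2 <- cbind(0.1 * u, 0.1 * u, 2 * u, 0.1 * u, 0.1 * u, 0.1 * u,
                0.1 * u, 0.1 * u, 2 * u)
  rec2 <- make_record(hbo2, -0.3 * hbo2, fs = fs, rest_n = 100)
  expect_equal(select_most_active_channel(rec2), 3)
})

test_that("threshold calibration reproduces the closed-form radii", {
  expect_equal(resting_radius(c(0.1, 0, 0.1), c(0, 0.2, 0.1)), 0.2)
  expect_equal(outer_radius(0.2, 1.0, 0.1), 0.53)
  # all-zero record gives r1 = r2 = 0
  z <- matrix(0, 400, 2)
  recz <- make_record(z, z, fs = 10, rest_n = 100)
  circz <- calibrate_thresholds(recz, most_active = 1)
  expect_equal(unname(circz$r1), c(0, 0))
  expect_equal(unname(circz$r2), c(0, 0))
})

test_that("calibrated circles satisfy r2 >= r1 on random records", {
  for (seed in 1:3) {
    cfg <- synth_config(n_channels = 4, active_channels = c(1L, 3L))
    circ <- calibrate_thresholds(bandpass(generate_dataset(cfg, seed)))
    expect_true(all(circ$r2 >= circ$r1))
    expect_s3_class(circ, "threshold_circles")
  }
  # global mode shares the most active channel's r1
  cfg <- synth_config(n_channels = 4, active_channels = c(1L, 3L))
  circ <- calibrate_thresholds(bandpass(generate_dataset(cfg, 1)),
                               mode = "global")
  expect_equal(length(unique(circ$r1)), 1L)
})
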