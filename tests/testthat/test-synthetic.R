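test_that("noise generator: zero params, determinism, Gaussian sd", {
  p0 <- noise_params(cardiac = c(0, 1, 0), mayer = c(0, 0.1, 0),
                     respiration = c(0, 0.25, 0), sd = 0, drift = 0)
  expect_equal(generate_noise(p0, 100, 10, seed = 3), numeric(100))
  p1 <- noise_params()
  expect_identical(generate_noise(p1, 500, 10, seed = 42),
                   generate_noise(p1, 500, 10, seed = 42))
  pg <- noise_params(cardiac = c(0, 1, 0), mayer = c(0, 0.1, 0),
                     respiration = c(0, 0.25, 0), sd = 1, drift = 0)
  x <- generate_noise(pg, 10000, 10, seed = 7)
  expect_gt(sd(x), 0.97)
  expect_lt(sd(x), 1.03)
})

test_that("noise parameter validation", {
  expect_error(noise_params(sd = -1), ">= 0")
  expect_error(noise_params(cardiac = c(1, -2, 0)), "> 0")
})

test_that("channel generator realizes the response-plus-noise model", {
  fs <- 9.19
  s <- stimulus_boxcar(fs, 10, 20, 2)
  h <- canonical_hrf(hrf_params(), 30, fs)
  u <- desired_hrf(h, s)
  dip <- dip_response(h, s)
  quiet <- noise_params(cardiac = c(0, 1, 0), mayer = c(0, 0.1, 0),
                        respiration = c(0, 0.25, 0), sd = 0, drift = 0)
  # pure response without noise or dip
  sp <- channel_spec(1, hbo_gain = 2, dip_gain = 0)
  xy <- generate_channel(sp, u, dip, quiet, seed = 1)
  expect_equal(xy$hbo, 2 * u$u)
  # proportional HbO/HbR are perfectly anti-correlated
  expect_equal(cor(xy$hbo, xy$hbr), -1)
  # non-active channel without noise is exactly zero
  sp0 <- channel_spec(2, active = FALSE, dip_gain = 0)
  expect_equal(generate_channel(sp0, u, dip, quiet, seed = 1)$hbo,
               numeric(length(u$u)))
})

test_that("channel_spec enforces the activity/gain contract", {
  expect_error(channel_spec(1, active = TRUE, hbo_gain = 0), "nonzero")
  expect_error(channel_spec(1, active = FALSE, hbo_gain = 1), "non-active")
})

test_that("injected dip drives early HbO down, HbR up, into dip phases", {
  fs <- 9.19
  s <- stimulus_boxcar(fs, 10, 20, 1)
  h <- canonical_hrf(hrf_params(), 30, fs)
  u <- desired_hrf(h, s)
  dip <- dip_response(h, s)
  quiet <- noise_params(cardiac = c(0, 1, 0), mayer = c(0, 0.1, 0),
                        respiration = c(0, 0.25, 0), sd = 0, drift = 0)
  sp <- channel_spec(1, hbo_gain = 1, dip_gain = 0.5)
  xy <- generate_channel(sp, u, dip, quiet, seed = 1)
  t <- (seq_along(xy$hbo) - 1) / fs
  early <- t > 0.2 & t <= 2
  expect_lt(min(xy$hbo[early]), 0)
  expect_gt(max(xy$hbr[early]), 0)
  ph <- classify_phase(xy$hbo[early], xy$hbr[early])
  expect_true(any(ph %in% 3:5))
})

test_that("dataset has the paradigm geometry and is seed-reproducible", {
  cfg <- synth_config(n_channels = 6, active_channels = c(2L, 5L))
  rec <- generate_dataset(cfg, seed = 9)
  expect_equal(nrow(rec$hbo), 275 + 2 * 1650)   # 30 s rest + 2 sessions
  expect_equal(ncol(rec$hbo), 6)
  expect_equal(ncol(rec$hbr), 6)
  expect_equal(rec$segments$segment, c("rest", "session1", "session2"))
  expect_equal(diff(segment_indices(rec, "session1"))[1], 1)
  expect_length(segment_indices(rec, "session1"), 1650)
  rec2 <- generate_dataset(cfg, seed = 9)
  expect_identical(rec, rec2)
  expect_false(identical(rec$hbo, generate_dataset(cfg, seed = 10)$hbo))
  # default montage matches the advertised study shape
  expect_equal(ncol(generate_dataset(synth_config(
    n_trials = 1, n_sessions = 1, rest_prefix_s = 5), seed = 1)$hbo), 36)
})

test_that("task response grows with HbO gain (trial-average contrast)", {
  contrasts <- vapply(c(0.5, 1, 2), function(g) {
    cfg <- synth_config(n_channels = 1, active_channels = 1L, hbo_gain = g,
                        gain_jitter = 0, n_sessions = 1)
    rec <- generate_dataset(cfg, seed = 4)
    sess <- segment_indices(rec, "session1")
    rest <- segment_indices(rec, "rest")
    task <- sess[rep(rec$stimulus$s[sess] == 1, 1)]
    mean(rec$hbo[task, 1]) - mean(rec$hbo[rest, 1])
  }, numeric(1))
  expect_true(all(diff(contrasts) > 0))
})
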