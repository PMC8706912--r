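test_that("templates are seeded, smooth and separated when asked", {
  cfg <- synthetic_config(H = 3, G = 2, axes_per_sensor = 3, base_len = 60,
                          separation = 1, seed = 14)
  t1 <- make_class_templates(cfg)
  t2 <- make_class_templates(cfg)
  expect_identical(t1, t2)
  expect_length(t1, 3)
  expect_length(t1[[1]], 6)
  expect_length(t1[[1]][[1]], 60)

  # full separation keeps classes apart in L2 on every channel ensemble
  d12 <- sqrt(sum((unlist(t1[[1]]) - unlist(t1[[2]]))^2))
  expect_gt(d12, 0.5)

  # single class is fine
  cfg1 <- synthetic_config(H = 1, seed = 2)
  expect_length(make_class_templates(cfg1), 1)

  # zero separation collapses all classes onto the common waveform
  cfg0 <- synthetic_config(H = 3, separation = 0, seed = 5)
  t0 <- make_class_templates(cfg0)
  expect_equal(t0[[1]], t0[[3]])
})

test_that("the corruption model is identity at zero intensity and preserves peaks", {
  set.seed(50)
  wf <- exp(-0.5 * ((1:100 - 40) / 6)^2) # single bump at 40
  expect_equal(apply_nonlinear_warp(wf, 0, 0L, 0, seed = 3), wf)

  # warp + latency move the peak but keep its amplitude; repeat over seeds
  for (s in 1:20) {
    out <- apply_nonlinear_warp(wf, 0.3, 5L, 0, seed = s)
    expect_lt(abs(max(out) - max(wf)), 0.02) # interpolation error only
    expect_lt(abs(which.max(out) - 40), 5 + 0.3 * 100 + 1)
  }

  # warp maps must be strictly increasing with fixed endpoints
  m <- movefuse:::random_warp_map(80, 0.4, 8)
  expect_equal(m[1], 1)
  expect_equal(m[80], 80)
  expect_true(all(diff(m) > 0))
})

test_that("dataset generation is reproducible bookkeeping with shared warps", {
  cfg <- synthetic_config(H = 4, G = 2, axes_per_sensor = 3, n_trials = 30,
                          warp_intensity = 0.2, latency_range = 5,
                          noise_sd = 0, base_len = 40, seed = 8)
  recs <- generate_dataset(cfg)
  expect_length(recs, 120)
  expect_true(all(vapply(recs, rec_MG, integer(1)) == 6L))
  expect_identical(sort(unique(labels_of(recs))), 1:4)

  # same master seed -> identical ensemble; different seed -> different
  recs2 <- generate_dataset(cfg)
  expect_identical(recs, recs2)
  cfg_b <- synthetic_config(H = 4, G = 2, axes_per_sensor = 3, n_trials = 30,
                            warp_intensity = 0.2, latency_range = 5,
                            noise_sd = 0, base_len = 40, seed = 9)
  expect_false(identical(generate_dataset(cfg_b), recs))

  # per-sensor shared warp: with a monotone template the warped channels of
  # one sensor stay identical when templates coincide across axes; check
  # via the warp maps directly by regenerating with zero noise and
  # comparing within- vs across-sensor channel alignment of one trial
  tpl <- make_class_templates(cfg, seed = 1)
  same_map <- movefuse:::random_warp_map(40, 0.3, 8)
  a <- apply_nonlinear_warp(tpl[[1]][[1]], 0.3, 0L, 0, warp_map = same_map,
                            shift = 0L)
  b <- apply_nonlinear_warp(tpl[[1]][[1]], 0.3, 0L, 0, warp_map = same_map,
                            shift = 0L)
  expect_identical(a, b)
})

test_that("duration jitter produces unequal raw lengths", {
  cfg <- synthetic_config(H = 2, n_trials = 10, base_len = 50,
                          len_jitter = 6, seed = 3)
  recs <- generate_dataset(cfg)
  lens <- vapply(recs, function(r) length(r$signals[[1]]$samples), integer(1))
  expect_gt(length(unique(lens)), 1)
  expect_true(all(abs(lens - 50) <= 6))
})

test_that("warping a template leaves it closer to its own class than to others", {
  cfg <- benchmark_config(seed = 19)
  tpl <- make_class_templates(cfg)
  own <- numeric(0); cross <- numeric(0)
  for (s in 1:40) {
    warped <- apply_nonlinear_warp(tpl[[1]][["s1.1"]], cfg$warp_intensity,
                                   cfg$latency_range, 0, seed = 1000 + s)
    own <- c(own, dtw_align(warped, tpl[[1]][["s1.1"]])$value)
    other <- 1 + (s %% (cfg$H - 1))
    cross <- c(cross, dtw_align(warped, tpl[[1 + other]][["s1.1"]])$value)
  }
  expect_true(all(own <= cross))
})

test_that("noise monotonically degrades global-matrix DTW accuracy", {
  accs <- vapply(c(0, 0.8, 2.5), function(sig) {
    cfg <- synthetic_config(H = 4, G = 2, axes_per_sensor = 3, n_trials = 6,
                            base_len = 40, warp_intensity = 0.15,
                            latency_range = 4, noise_sd = sig, seed = 31)
    recs <- generate_dataset(cfg)
    repeated_holdout(recs, "dtw3", reps = 3, seed = 17)$mean_accuracy
  }, numeric(1))
  expect_true(accs[1] >= accs[2] && accs[2] >= accs[3])
  expect_equal(accs[1], 100)
})
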