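test_that("duration_normalize interpolates linearly and preserves endpoints", {
  expect_equal(duration_normalize(c(1, 2, 3), 3), c(1, 2, 3))
  expect_equal(duration_normalize(c(0, 2), 3), c(0, 1, 2))

  # piecewise-linear oracle evaluated by hand at positions 1, 1.5, ..., 5
  x <- c(0, 1, 4, 9, 16)
  out <- duration_normalize(x, 9)
  expect_equal(out, c(0, 0.5, 1, 2.5, 4, 6.5, 9, 12.5, 16))
  expect_equal(out[1], x[1])
  expect_equal(out[9], x[5])
  expect_true(all(diff(out) >= 0))

  # idempotent at the target length
  expect_equal(duration_normalize(out, 9), out)

  s <- uniaxial_signal(c(0, 2), sensor = 2, axis = 1)
  s2 <- duration_normalize(s, 5)
  expect_s3_class(s2, "uniaxial_signal")
  expect_length(s2$samples, 5)
  expect_identical(s2$sensor, 2L)

  expect_error(duration_normalize(c(1, 2, 3), 1), "target_len")
  expect_error(duration_normalize(c(1, NA, 3), 5), "finite")
})

test_that("duration targets are rounded means at the right granularity", {
  recs <- list(
    mk_rec(list("1.1" = rnorm(90), "2.1" = rnorm(110)), label = 1),
    mk_rec(list("1.1" = rnorm(90), "2.1" = rnorm(110)), label = 1)
  )
  spec <- fit_normalization(recs, "GMI")
  expect_identical(compute_target_lengths(spec), 100L)

  one <- list(mk_rec(list("1.1" = rnorm(75), "1.2" = rnorm(75),
                          "2.1" = rnorm(75)), label = 1))
  expect_identical(compute_target_lengths(fit_normalization(one, "GCI")), 75L)

  # mean of {80, 95, 101} is 92.0 exactly; round half away from zero
  three <- list(mk_rec(list("1.1" = rnorm(80)), label = 1),
                mk_rec(list("1.1" = rnorm(95)), label = 1),
                mk_rec(list("1.1" = rnorm(101)), label = 1))
  expect_identical(compute_target_lengths(fit_normalization(three, "GMI")), 92L)

  # per-sensor targets for the local-matrix model
  lmi <- list(mk_rec(list("1.1" = rnorm(80), "1.2" = rnorm(90),
                          "2.1" = rnorm(50)), label = 1))
  tl <- compute_target_lengths(fit_normalization(lmi, "LMI"))
  expect_identical(unname(tl), c(85L, 50L))

  # vector model leaves durations free
  expect_null(compute_target_lengths(fit_normalization(lmi, "VI")))
  expect_error(fit_normalization(list(), "GMI"), "empty")
})

test_that("min-max statistics pool over the training set and do not clip", {
  r1 <- mk_rec(list("1.1" = c(-1, 1)), label = 1)
  r2 <- mk_rec(list("1.1" = c(0, 3)), label = 1)
  st <- minmax_fit(list(r1, r2))
  expect_equal(st$min, -1)
  expect_equal(st$max, 3)

  s <- uniaxial_signal(c(1, 12, 5), sensor = 1, axis = 1)
  mapped <- minmax_apply(s, tibble::tibble(sensor = 1L, axis = 1L,
                                           min = 0, max = 10))
  expect_equal(mapped$samples, c(0.1, 1.2, 0.5)) # 12 extrapolates past 1

  mapped2 <- minmax_apply(s, st)
  expect_equal(mapped2$samples[1], (1 - -1) / 4)

  const <- mk_rec(list("1.1" = c(2, 2, 2)), label = 1)
  expect_error(minmax_fit(list(const)), "sensor 1 axis 1")
})

test_that("build_input produces the four model payloads coherently", {
  set.seed(9)
  recs <- lapply(1:2, function(i) {
    mk_rec(stats::setNames(lapply(1:6, function(j) rnorm(100)),
                           c("1.1", "1.2", "1.3", "2.1", "2.2", "2.3")),
           label = i)
  })
  spec <- fit_normalization(recs, "GMI")
  gmi <- build_input(recs[[1]], "GMI", spec)
  expect_identical(dim(gmi$payload), c(6L, 100L))

  spec_gci <- fit_normalization(recs, "GCI")
  gci <- build_input(recs[[1]], "GCI", spec_gci)
  expect_identical(dim(gci$payload), c(3L, 100L, 2L))

  # depth-frame g of the cuboid is the sensor-g local matrix
  spec_lmi <- fit_normalization(recs, "LMI")
  lmi <- build_input(recs[[1]], "LMI", spec_lmi)
  for (g in 1:2) expect_equal(gci$payload[, , g], lmi$payload[[g]])

  # global matrix is the row-concatenation of the local matrices when the
  # per-sensor and global targets coincide (all raw durations equal here)
  expect_equal(gmi$payload, do.call(rbind, lmi$payload))

  # losslessness: raw durations already at target, no amplitude mapping
  expect_equal(gmi$payload[4, ], rec_channel(recs[[1]], 2, 1)$samples)

  # vector model passes channels through untouched
  vi <- build_input(recs[[1]], "VI", fit_normalization(recs, "VI"))
  expect_length(vi$payload, 6)
  expect_equal(vi$payload[["s1.2"]], rec_channel(recs[[1]], 1, 2)$samples)

  one <- mk_rec(list("1.1" = c(1, 2, 3)), label = 1)
  vi1 <- build_input(one, "VI", fit_normalization(list(one), "VI"))
  expect_equal(vi1$payload[[1]], c(1, 2, 3))

  # cuboid needs equal axis counts across sensors
  uneq <- mk_rec(list("1.1" = rnorm(10), "1.2" = rnorm(10),
                      "2.1" = rnorm(10)), label = 1)
  spec_u <- fit_normalization(list(uneq), "GMI")
  expect_error(build_input(uneq, "GCI", spec_u), "not applicable")
})

test_that("energy segmentation recovers bursts and merges nearby runs", {
  n <- 300
  burst <- function(from, to) {
    x <- numeric(n); x[from:to] <- 1; x
  }
  one <- mk_rec(list("1.1" = burst(50, 80), "1.2" = numeric(n) + 0))
  seg <- segment_energy(one, window = 5, threshold_frac = 0.1, min_gap = 10)
  expect_identical(nrow(seg), 1L)
  expect_lte(seg$start[1], 50L)
  expect_gte(seg$end[1], 80L)
  expect_lte(seg$end[1] - seg$start[1], 31L + 2L * 5L)

  two <- mk_rec(list("1.1" = burst(40, 60) + burst(200, 230)))
  seg2 <- segment_energy(two, window = 5, threshold_frac = 0.1, min_gap = 20)
  expect_identical(nrow(seg2), 2L)
  expect_true(seg2$start[2] > seg2$end[1])

  merged <- segment_energy(
    mk_rec(list("1.1" = burst(40, 60) + burst(75, 95))),
    window = 5, threshold_frac = 0.1, min_gap = 30)
  expect_identical(nrow(merged), 1L)

  silent <- mk_rec(list("1.1" = numeric(n) + 0, "1.2" = numeric(n) + 0))
  expect_identical(nrow(segment_energy(silent)), 0L)
})

test_that("recording invariants are enforced", {
  expect_error(uniaxial_signal(c(1), 1, 1), "at least 2")
  expect_error(uniaxial_signal(c(1, Inf), 1, 1), "finite")
  s1 <- uniaxial_signal(1:5, 1, 1)
  expect_error(movement_recording(list(s1, s1)), "exactly once")
  s3 <- uniaxial_signal(1:5, 1, 3)
  expect_error(movement_recording(list(s1, s3)), "numbered")
  rec <- mk_rec(list("1.1" = 1:4, "1.2" = 5:8, "2.1" = 1:6), label = 2)
  expect_identical(rec_G(rec), 2L)
  expect_identical(rec_mg(rec), c(2L, 1L))
  expect_identical(rec_MG(rec), 3L)
  sub <- subset_channel(rec, 2, 1)
  expect_identical(rec_MG(sub), 1L)
  expect_equal(sub$signals[[1]]$samples, as.numeric(1:6))
  expect_identical(sub$label, 2L)
})
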