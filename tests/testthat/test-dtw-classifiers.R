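test_that("central-tendency estimators match direct computation", {
  set.seed(31)
  x <- rnorm(11)
  expect_equal(ct_estimate(x, "mean"), mean(x))
  expect_equal(ct_estimate(x, "median"), median(x))
  expect_equal(ct_estimate(x, "trimean"),
               unname((quantile(x, .25) + 2 * quantile(x, .5) +
                         quantile(x, .75)) / 4))

  # sort-and-slice oracle for the 20% trimmed mean of five values:
  # drop one minimum and one maximum, average the rest
  y <- c(4, -1, 10, 2, 3)
  expect_equal(ct_estimate(y, "trimmed_mean", alpha = 0.2),
               mean(sort(y)[2:4]))

  # winsorized mean pins the tails to the alpha quantiles
  q <- quantile(y, c(0.2, 0.8), names = FALSE)
  expect_equal(ct_estimate(y, "winsorized_mean", alpha = 0.2),
               mean(pmin(pmax(y, q[1]), q[2])))
})

test_that("templates are element-wise class averages", {
  r1 <- mk_rec(list("1.1" = c(0, 0, 0), "1.2" = c(1, 2, 3)), label = 1)
  r2 <- mk_rec(list("1.1" = c(2, 2, 2), "1.2" = c(1, 2, 3)), label = 1)
  r3 <- mk_rec(list("1.1" = c(5, 5, 5), "1.2" = c(0, 0, 0)), label = 2)
  r4 <- mk_rec(list("1.1" = c(5, 5, 5), "1.2" = c(0, 0, 0)), label = 2)
  train <- list(r1, r2, r3, r4)
  spec <- fit_normalization(train, "VI")
  tpl <- fit_templates(train, "VI", spec)
  expect_equal(tpl$templates[[1]][["s1.1"]], c(1, 1, 1))
  expect_equal(tpl$templates[[1]][["s1.2"]], c(1, 2, 3))
  # two identical recordings: template equals either one
  expect_equal(tpl$templates[[2]][["s1.1"]], c(5, 5, 5))

  # per-time-point trimmed mean against a sort-and-slice oracle
  set.seed(4)
  vals <- replicate(5, rnorm(6))
  five <- lapply(seq_len(5), function(i) {
    mk_rec(list("1.1" = vals[, i]), label = 1)
  })
  spec5 <- fit_normalization(five, "GMI")
  tpl5 <- fit_templates(five, "GMI", spec5, estimator = "trimmed_mean",
                        alpha = 0.2)
  oracle <- apply(vals, 1, function(v) mean(sort(v)[2:4]))
  expect_equal(as.numeric(tpl5$templates[[1]]), oracle)

  expect_error(fit_templates(list(r1, r2), "VI", spec, H = 2), "class")
})

test_that("dtw1 averages per-channel discrepancies and recovers templates", {
  recs <- clean_ensemble(H = 3, n_trials = 4, base_len = 30)
  spec <- fit_normalization(recs, "VI")
  tpl <- fit_templates(recs, "VI", spec)
  # zero corruption: every trial equals its class template
  p <- dtw1_classify(recs[[5]], tpl)
  expect_identical(p$class, recs[[5]]$label)
  expect_equal(p$scores[recs[[5]]$label], 0)
  expect_length(p$scores, 3)
  expect_true(all(p$scores >= 0))

  # fused score equals the hand-averaged per-channel alignments
  fi <- build_input(recs[[1]], "VI", spec)
  manual <- mean(vapply(names(fi$payload), function(ch) {
    dtw_align(fi$payload[[ch]], tpl$templates[[2]][[ch]])$value
  }, numeric(1)))
  expect_equal(p2 <- dtw1_classify(recs[[1]], tpl)$scores[2], manual)

  # single channel, single class: always class 1
  one <- lapply(1:2, function(i) mk_rec(list("1.1" = rnorm(10)), label = 1))
  spec1 <- fit_normalization(one, "VI")
  tpl1 <- fit_templates(one, "VI", spec1, H = 1)
  expect_identical(dtw1_classify(one[[1]], tpl1)$class, 1L)
})

test_that("dtw2 fuses per-sensor matrix discrepancies", {
  recs <- clean_ensemble(H = 3, n_trials = 4, base_len = 30)
  spec <- fit_normalization(recs, "LMI")
  tpl <- fit_templates(recs, "LMI", spec)
  p <- dtw2_classify(recs[[9]], tpl)
  expect_identical(p$class, recs[[9]]$label)

  # random instance: fused scores equal hand-averaged per-sensor alignments
  fi <- build_input(recs[[2]], "LMI", spec)
  for (h in 1:3) {
    manual <- mean(vapply(1:2, function(g) {
      dtw_align(fi$payload[[g]], tpl$templates[[h]][[g]])$value
    }, numeric(1)))
    expect_equal(p0 <- dtw2_classify(recs[[2]], tpl)$scores[h], manual)
  }

  # when the test matches sensor 1 templates exactly, only sensor 2 counts
  expect_equal(dtw2_classify(recs[[2]], tpl)$scores[recs[[2]]$label], 0)
})

test_that("dtw3 aligns the global matrix and collapses to dtw1 for 1 channel", {
  recs <- clean_ensemble(H = 2, n_trials = 3, base_len = 25)
  spec <- fit_normalization(recs, "GMI")
  tpl <- fit_templates(recs, "GMI", spec)
  p <- dtw3_classify(recs[[4]], tpl)
  expect_identical(p$class, recs[[4]]$label)
  expect_equal(p$scores[recs[[4]]$label], 0)

  # scores equal direct global-matrix alignments
  fi <- build_input(recs[[1]], "GMI", spec)
  direct <- vapply(1:2, function(h) {
    dtw_align(fi$payload, tpl$templates[[h]])$value
  }, numeric(1))
  expect_equal(dtw3_classify(recs[[1]], tpl)$scores, direct)

  # a 1-sensor 1-axis recording: global matrix is the channel vector
  ones <- lapply(1:4, function(i) {
    mk_rec(list("1.1" = rnorm(20)), label = (i - 1L) %/% 2L + 1L)
  })
  spec1v <- fit_normalization(ones, "VI")
  spec1g <- fit_normalization(ones, "GMI")
  t1 <- fit_templates(ones, "VI", spec1v)
  t3 <- fit_templates(ones, "GMI", spec1g)
  expect_equal(dtw1_classify(ones[[1]], t1)$scores,
               dtw3_classify(ones[[1]], t3)$scores)
})

test_that("with one sensor the per-sensor and global models coincide", {
  set.seed(12)
  recs <- lapply(1:6, function(i) {
    mk_rec(list("1.1" = rnorm(15), "1.2" = rnorm(15), "1.3" = rnorm(15)),
           label = (i - 1L) %/% 3L + 1L)
  })
  spec_l <- fit_normalization(recs, "LMI")
  spec_g <- fit_normalization(recs, "GMI")
  t2 <- fit_templates(recs, "LMI", spec_l)
  t3 <- fit_templates(recs, "GMI", spec_g)
  for (r in recs[1:3]) {
    p2 <- dtw2_classify(r, t2)
    p3 <- dtw3_classify(r, t3)
    expect_identical(p2$class, p3$class)
    expect_equal(p2$scores, p3$scores)
  }
})

test_that("least-discrepancy ties resolve to the lowest class index", {
  expect_identical(movefuse:::argmin_tie_low(c(2, 2)), 1L)
  expect_identical(movefuse:::argmin_tie_low(c(3, 1, 1)), 2L)
})
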