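test_that("convolution and pooling dimension algebra", {
  # "same": p = (f-1)/2 and stride 1 preserve spatial dims
  expect_identical(conv_output_dims(c(6, 100, 1), c(3, 3, 1), 32, p = 1),
                   c(6L, 100L, 32L))
  # "valid" arithmetic
  expect_identical(conv_output_dims(c(6, 100, 1), c(1, 3, 1), 32, p = 0)[2],
                   98L)
  expect_identical(pool_output_dims(c(6, 100, 32), c(2, 2), 2),
                   c(3L, 50L, 32L))
  expect_identical(pool_output_dims(c(1, 6, 8), c(1, 2), 2), c(1L, 3L, 8L))
  expect_error(conv_output_dims(c(2, 5, 1), c(5, 3, 1), 8, p = 0), "larger")
  expect_error(conv_output_dims(c(4, 5, 1), c(3, 3, 2), 8, p = 1), "depth")
})

test_that("the four architectures follow the fixed filter geometry", {
  a1 <- build_architecture("cnn1", c(1, 100, 1), 6)
  expect_equal(a1$filters[[1]], c(1, 3, 1))
  expect_equal(a1$filters[[2]], c(1, 3, 32))
  expect_equal(a1$pool_size, c(1L, 2L))

  a2 <- build_architecture("cnn2", c(3, 100, 1), 6)
  expect_equal(a2$filters[[1]], c(3, 3, 1))
  expect_equal(a2$filters[[2]], c(3, 3, 32))

  a3 <- build_architecture("cnn3", c(6, 100, 1), 6)
  expect_equal(a3$dims$conv1, c(6L, 100L, 32L)) # "same" preserves dims
  expect_equal(a3$dims$conv2, c(6L, 100L, 32L))
  expect_equal(a3$dims$pool, c(3L, 50L, 32L))

  a4 <- build_architecture("cnn4", c(3, 100, 2), 6)
  expect_equal(a4$filters[[1]], c(3, 3, 2)) # depth-spanning first layer
  expect_equal(a4$filters[[2]], c(3, 3, 32))
  expect_equal(a4$dims$conv1[1:2], c(3L, 100L)) # cuboid conv gives a matrix
  expect_equal(a4$H, 6L)

  expect_error(build_architecture("cnn1", c(3, 100, 1), 6), "vector inputs")
})

test_that("dimension chain holds across random input sizes", {
  set.seed(88)
  for (i in 1:25) {
    w <- sample(20:150, 1)
    hgt <- sample(2:8, 1)
    G <- sample(2:3, 1)
    shapes <- list(cnn1 = c(1, w, 1), cnn2 = c(hgt, w, 1),
                   cnn3 = c(hgt, w, 1), cnn4 = c(hgt, w, G))
    for (tag in names(shapes)) {
      arch <- build_architecture(tag, shapes[[tag]], 5)
      d1 <- conv_output_dims(arch$input_shape, arch$filters[[1]],
                             arch$n_filters[1], arch$pad[[1]], 1)
      d2 <- conv_output_dims(d1, arch$filters[[2]], arch$n_filters[2],
                             arch$pad[[2]], 1)
      dp <- pool_output_dims(d2, arch$pool_size, arch$pool_stride)
      expect_identical(arch$dims$conv1, d1)
      expect_identical(arch$dims$conv2, d2)
      expect_identical(arch$dims$pool, dp)
      expect_identical(arch$flat_len, prod(dp))
      # "same" convolutions preserve the spatial extent
      expect_identical(d1[1:2], arch$input_shape[1:2])
    }
  }
})

test_that("forward pass matches a hand-rolled computation on a toy net", {
  # 1x3 input, one 1x3 filter, identity-like weights, known arithmetic
  arch <- build_architecture("cnn1", c(1, 3, 1), 2, n_filters = c(1, 1),
                             fc_width = 2)
  net <- list(arch = arch, ops = movefuse:::build_ops(arch))
  p <- movefuse:::init_params(arch)
  p$W1 <- matrix(c(0, 1, 0), 3, 1) # center tap: identity under "same"
  p$b1 <- 0
  p$W2 <- matrix(c(0, 1, 0), 3, 1)
  p$b2 <- 0
  p$Wf1 <- matrix(0, arch$flat_len, 2); p$Wf1[1, 1] <- 1
  p$bf1 <- c(0, 0)
  p$Wf2 <- matrix(c(1, 0, -1, 0), 2, 2) # hidden unit 1 -> logits (v, -v)
  p$bf2 <- c(0, 0)
  net$params <- p
  x <- c(2, -1, 3)
  # conv1 = conv2 = relu(x) = (2, 0, 3); pool (1x2 stride 2) -> max(2, 0) = 2
  # FC1: sigmoid(2) in unit 1; logits (sigmoid(2), -sigmoid(2))
  s <- 1 / (1 + exp(-2))
  expected <- exp(c(s, -s)) / sum(exp(c(s, -s)))
  got <- forward_posteriors(structure(net, class = "trained_cnn"), x)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("posteriors are probability vectors and fuse by averaging", {
  set.seed(6)
  recs <- clean_ensemble(H = 2, n_trials = 6, base_len = 24)
  spec <- fit_normalization(recs, "GMI")
  fit <- train_model(recs, "cnn3", spec,
                     hyper = list(epochs = 3, val_frac = 0), seed = 2)
  res <- cnn_classify(fit, recs[1:5])
  expect_equal(colSums(res$posteriors), rep(1, 5), tolerance = 1e-6)
  expect_true(all(res$posteriors >= 0))

  expect_equal(fuse_posteriors(list(c(1, 0), c(0, 1))), c(0.5, 0.5))
  expect_equal(fuse_posteriors(list(c(0.9, 0.05, 0.05))), c(0.9, 0.05, 0.05))
  expect_equal(fuse_posteriors(list(c(1, .4, .1), c(.25, .3, .25),
                                    c(.25, .2, .25))), c(0.5, 0.3, 0.2))
  expect_error(fuse_posteriors(list(c(1, 0), c(1, 0, 0))), "length")

  expect_identical(decide(c(0.1, 0.7, 0.2)), 2L)
  expect_identical(decide(c(1, 1, 1) / 3), 1L) # tie -> lowest index
  # softmax shift invariance: adding a constant to logits leaves the
  # decision unchanged
  z <- c(0.3, -1, 2)
  expect_identical(decide(exp(z) / sum(exp(z))),
                   decide(exp(z + 5) / sum(exp(z + 5))))
})

test_that("training is reproducible and fits a separable problem", {
  recs <- clean_ensemble(H = 3, n_trials = 6, base_len = 30, seed = 21)
  spec <- fit_normalization(recs, "GCI")
  fit1 <- train_model(recs, "cnn4", spec,
                      hyper = list(epochs = 12, val_frac = 0), seed = 9)
  fit2 <- train_model(recs, "cnn4", spec,
                      hyper = list(epochs = 12, val_frac = 0), seed = 9)
  expect_identical(fit1$nets[[1]]$log$loss, fit2$nets[[1]]$log$loss)
  # zero-corruption ensemble is trivially separable
  res <- cnn_classify(fit1, recs)
  expect_equal(mean(res$class == labels_of(recs)), 1)
  # loss decreases overall
  lg <- fit1$nets[[1]]$log$loss
  expect_lt(lg[length(lg)], lg[1])
})

test_that("net counts follow the fusion structure and labels permute decisions", {
  recs <- clean_ensemble(H = 3, n_trials = 4, base_len = 24, seed = 33)
  spec_v <- fit_normalization(recs, "VI")
  spec_l <- fit_normalization(recs, "LMI")
  spec_g <- fit_normalization(recs, "GMI")
  spec_c <- fit_normalization(recs, "GCI")
  hy <- list(epochs = 10, val_frac = 0)
  expect_length(train_model(recs, "cnn1", spec_v, hy, seed = 1)$nets, 6)
  expect_length(train_model(recs, "cnn2", spec_l, hy, seed = 1)$nets, 2)
  expect_length(train_model(recs, "cnn3", spec_g, hy, seed = 1)$nets, 1)
  expect_length(train_model(recs, "cnn4", spec_c, hy, seed = 1)$nets, 1)

  # permuting the class labels permutes the decisions on this separable set
  perm <- c(3L, 1L, 2L)
  recs_p <- lapply(recs, function(r) { r$label <- perm[r$label]; r })
  hy2 <- list(epochs = 30, val_frac = 0)
  f0 <- train_model(recs, "cnn3", spec_g, hy2, seed = 5)
  fp <- train_model(recs_p, "cnn3", spec_g, hy2, seed = 5)
  d0 <- cnn_classify(f0, recs)$class
  dp <- cnn_classify(fp, recs)$class
  expect_identical(dp, perm[d0])

  # missing class errors
  bad <- Filter(function(r) r$label != 2, recs)
  expect_error(train_model(bad, "cnn3", spec_g, hy, seed = 1, H = 3),
               "class")
})
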