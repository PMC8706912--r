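# Minimal convolutional-network engine: conv layers run as correlation (no
# kernel flipping) as gather + BLAS matrix products; max pooling over
# non-overlapping windows; fully connected sigmoid + softmax head; Adam on
# the cross-entropy loss.
#
# Internal activation layout: a conv/pool activation is a matrix with one
# row per (spatial position, sample) pair -- position fastest, then sample
# -- and one column per channel. Patch extraction ("im2col") then becomes a
# single C-level row gather with a precomputed index, and the patch matrix
# can be reinterpreted as (positions*samples) x (patch*channels) without
# copying, so convolution is one gather plus one dense matrix product.

#' Convolution-layer output dimensions
#'
#' `H1 = 1 + floor((H0 - fh + 2p) / stride)` per spatial axis; the output
#' depth equals the number of filters.
#'
#' @param in_dims Integer vector `(H, W, D)` of the layer input.
#' @param filter_dims Integer vector `(fh, fw, depth)`; `depth` must equal
#'   the input depth.
#' @param n_filters Number of filters `K` in the layer.
#' @param p Zero-padding per spatial axis (scalar or `(ph, pw)`); `p = 0` is
#'   "valid" convolution, `p = (f - 1) / 2` with stride 1 is "same".
#' @param stride Convolution stride.
#' @return Integer vector `(H', W', K)`.
#' @export
conv_output_dims <- function(in_dims, filter_dims, n_filters, p = 0, stride = 1) {
  p <- rep_len(as.integer(p), 2L)
  if (filter_dims[3] != in_dims[3]) {
    stop("filter depth must equal input depth", call. = FALSE)
  }
  span <- c(in_dims[1] + 2 * p[1] - filter_dims[1],
            in_dims[2] + 2 * p[2] - filter_dims[2])
  if (any(span < 0)) stop("filter larger than padded input", call. = FALSE)
  as.integer(c(1 + span %/% stride, n_filters))
}

#' Pooling-layer output dimensions
#'
#' `H' = 1 + floor((H - fh) / stride)` per spatial axis; depth is preserved.
#'
#' @param in_dims Integer vector `(H, W, D)`.
#' @param pool_dims Integer vector `(fh, fw)`.
#' @param stride Pooling stride.
#' @return Integer vector `(H', W', D)`.
#' @export
pool_output_dims <- function(in_dims, pool_dims, stride) {
  span <- c(in_dims[1] - pool_dims[1], in_dims[2] - pool_dims[2])
  if (any(span < 0)) stop("pooling window larger than input", call. = FALSE)
  as.integer(c(1 + span %/% stride, in_dims[3]))
}

# Spatial index structure for a stride-1 "same"/"valid" convolution over an
# (h, w) plane: 0-based padded-plane gather indices per (output position,
# patch element), plus the embedding of the unpadded plane into the padded
# one. The heavy lifting (padding, gathers, scatter-adds, gemms) happens in
# the compiled layer kernels.
make_unfold <- function(h, w, fh, fw, ph, pw) {
  hp <- h + 2L * ph
  wp <- w + 2L * pw
  ho <- hp - fh + 1L
  wo <- wp - fw + 1L
  npos <- ho * wo
  fs <- fh * fw
  io <- rep(seq_len(ho), times = wo)
  jo <- rep(seq_len(wo), each = ho)
  gidx <- matrix(0L, npos, fs)
  f <- 0L
  for (fj in seq_len(fw)) {
    for (fi in seq_len(fh)) {
      f <- f + 1L
      gidx[, f] <- (io + fi - 2L) + (jo + fj - 2L) * hp
    }
  }
  rr <- rep(seq_len(h), times = w) + ph
  cc <- rep(seq_len(w), each = h) + pw
  pad_pos <- (rr - 1L) + (cc - 1L) * hp
  list(h = h, w = w, fh = fh, fw = fw, npos_in = h * w, plane = hp * wp,
       h_out = ho, w_out = wo, npos = npos, fs = fs, gidx = gidx,
       pad_pos = pad_pos)
}

# 0-based index map for non-overlapping max pooling over an (h, w) plane.
make_pool <- function(h, w, fh, fw, s) {
  ho <- (h - fh) %/% s + 1L
  wo <- (w - fw) %/% s + 1L
  npos <- ho * wo
  fs <- fh * fw
  io <- rep(seq_len(ho), times = wo)
  jo <- rep(seq_len(wo), each = ho)
  gidx <- matrix(0L, npos, fs)
  f <- 0L
  for (fj in seq_len(fw)) {
    for (fi in seq_len(fh)) {
      f <- f + 1L
      gidx[, f] <- ((io - 1L) * s + fi - 1L) + ((jo - 1L) * s + fj - 1L) * h
    }
  }
  list(npos_in = h * w, h_out = ho, w_out = wo, npos = npos, fs = fs,
       gidx = gidx)
}

# X: (npos_in * B) x C activation, W: (fs * C) x K filter bank (patch
# element fastest, then input channel), b: length-K bias.
conv_forward <- function(X, W, b, uf, B) {
  cpp_conv_fwd(X, W, b, uf$gidx, uf$pad_pos, uf$plane, B)
}

conv_backward <- function(dOut, cache, W, uf, B, need_dX = TRUE) {
  res <- cpp_conv_bwd(dOut, cache$mask, cache$Xpad, W, uf$gidx, uf$pad_pos,
                      uf$plane, B, need_dX)
  res$db <- as.numeric(res$db)
  res
}

pool_forward <- function(X, pl, B) {
  cpp_pool_fwd(X, pl$gidx, pl$npos_in, B)
}

pool_backward <- function(dOut, cache, pl, B, C) {
  cpp_pool_bwd(dOut, cache$amax, pl$gidx, pl$npos_in, B)
}

# (features, B) column-major input -> internal (h*w*B) x d layout.
to_internal <- function(A, h, w, d) {
  B <- ncol(A)
  if (d == 1L) {
    dim(A) <- c(h * w * B, 1L)
    A
  } else {
    X <- aperm(array(A, c(h * w, d, B)), c(1, 3, 2))
    dim(X) <- c(h * w * B, d)
    X
  }
}

# (npos * B) x K activation -> flattened (npos * K) x B feature matrix.
to_features <- function(A, npos, B) {
  K <- ncol(A)
  X <- aperm(array(A, c(npos, B, K)), c(1, 3, 2))
  dim(X) <- c(npos * K, B)
  X
}

from_features <- function(A, npos, B) {
  K <- length(A) / (npos * B)
  X <- aperm(array(A, c(npos, K, B)), c(1, 3, 2))
  dim(X) <- c(npos * B, K)
  X
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max), "-")
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

net_forward <- function(params, ops, A, keep_cache = FALSE) {
  B <- ncol(A)
  d0 <- ops$input_shape
  X0 <- to_internal(A, d0[1], d0[2], d0[3])
  c1 <- conv_forward(X0, params$W1, params$b1, ops$uf1, B)
  c2 <- conv_forward(c1$out, params$W2, params$b2, ops$uf2, B)
  p1 <- pool_forward(c2$out, ops$pool, B)
  Af <- to_features(p1$out, ops$pool$npos, B)
  Z1 <- crossprod(params$Wf1, Af) + params$bf1 # vector bias recycles by column
  H1 <- 1 / (1 + exp(-Z1))
  logits <- crossprod(params$Wf2, H1) + params$bf2
  probs <- softmax_cols(logits)
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs, B = B, c1 = c1, c2 = c2, p1 = p1, Af = Af, H1 = H1)
}

net_backward <- function(params, ops, cache, Y) {
  B <- cache$B
  dlogits <- (cache$probs - Y) / B
  dWf2 <- cache$H1 %*% t(dlogits)
  dbf2 <- rowSums(dlogits)
  dH1 <- params$Wf2 %*% dlogits
  dZ1 <- dH1 * cache$H1 * (1 - cache$H1)
  dWf1 <- cache$Af %*% t(dZ1)
  dbf1 <- rowSums(dZ1)
  dAf <- params$Wf1 %*% dZ1
  dPool <- from_features(dAf, ops$pool$npos, B)
  dC2 <- pool_backward(dPool, cache$p1, ops$pool, B, ncol(params$W2))
  g2 <- conv_backward(dC2, cache$c2, params$W2, ops$uf2, B, need_dX = TRUE)
  g1 <- conv_backward(g2$dX, cache$c1, params$W1, ops$uf1, B, need_dX = FALSE)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       Wf1 = dWf1, bf1 = dbf1, Wf2 = dWf2, bf2 = dbf2)
}

glorot <- function(nin, nout, dims) {
  lim <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

init_params <- function(arch) {
  f1 <- arch$filters[[1]]
  f2 <- arch$filters[[2]]
  K <- arch$n_filters
  list(
    W1 = glorot(prod(f1), K[1], c(prod(f1), K[1])),
    b1 = rep(0, K[1]),
    W2 = glorot(prod(f2), K[2], c(prod(f2), K[2])),
    b2 = rep(0, K[2]),
    Wf1 = glorot(arch$flat_len, arch$fc_width, c(arch$flat_len, arch$fc_width)),
    bf1 = rep(0, arch$fc_width),
    Wf2 = glorot(arch$fc_width, arch$H, c(arch$fc_width, arch$H)),
    bf2 = rep(0, arch$H)
  )
}

build_ops <- function(arch) {
  d0 <- arch$input_shape
  f1 <- arch$filters[[1]]
  f2 <- arch$filters[[2]]
  uf1 <- make_unfold(d0[1], d0[2], f1[1], f1[2], arch$pad[[1]][1],
                     arch$pad[[1]][2])
  d2 <- arch$dims$conv2
  uf2 <- make_unfold(d2[1], d2[2], f2[1], f2[2], arch$pad[[2]][1],
                     arch$pad[[2]][2])
  pool <- make_pool(d2[1], d2[2], arch$pool_size[1], arch$pool_size[2],
                    arch$pool_stride)
  list(input_shape = d0, uf1 = uf1, uf2 = uf2, pool = pool)
}

cross_entropy <- function(probs, Y) {
  -mean(colSums(Y * log(pmax(probs, 1e-12))))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

default_hyper <- function(hyper = list()) {
  utils::modifyList(list(
    lr = 1e-3, batch_size = 32L, epochs = 200L, patience = 10L,
    val_frac = 0.1, loss_tol = 1e-4
  ), hyper)
}

#' Train one convolutional network
#'
#' Fits the fixed conv-conv-pool-FC(sigmoid)-FC(softmax) architecture by
#' Adam on the cross-entropy loss, with optional early stopping on a
#' stratified validation split. Fully reproducible for a fixed seed and
#' thread count: the seed drives weight initialization, the validation
#' split and the epoch shuffles.
#'
#' @param X Feature matrix, one column per sample, rows in (height, width,
#'   depth) column-major order of the architecture's input shape.
#' @param y Integer class labels in 1..H.
#' @param arch A `cnn_architecture` from [build_architecture()].
#' @param hyper Named list overriding defaults `lr = 1e-3`,
#'   `batch_size = 32`, `epochs = 200`, `patience = 10`, `val_frac = 0.1`,
#'   `loss_tol = 1e-4` (stop once the training loss falls below it).
#' @param seed Integer seed for this net.
#' @return A `trained_cnn`: list with `params`, `arch`, `log` (tibble of
#'   per-epoch training and validation loss) and `seed`.
#' @export
train_cnn <- function(X, y, arch, hyper = list(), seed = 1L) {
  hyper <- default_hyper(hyper)
  n <- ncol(X)
  H <- arch$H
  stopifnot(length(y) == n, all(y >= 1L), all(y <= H))
  set.seed(seed)
  ops <- build_ops(arch)
  params <- init_params(arch)
  state <- adam_init(params)
  Yall <- matrix(0, H, n)
  Yall[cbind(y, seq_len(n))] <- 1

  val_idx <- integer(0)
  if (hyper$val_frac > 0 && n >= 10L) {
    val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
      k <- floor(length(ix) * hyper$val_frac)
      if (k > 0) sample(ix, k) else integer(0)
    }), use.names = FALSE)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  best <- list(loss = Inf, params = params, epoch = 0L)
  log_epoch <- integer(0); log_loss <- numeric(0); log_val <- numeric(0)
  stall <- 0L
  for (epoch in seq_len(hyper$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / hyper$batch_size))
    ep_loss <- 0
    for (b in batches) {
      cache <- net_forward(params, ops, X[, b, drop = FALSE], keep_cache = TRUE)
      Yb <- Yall[, b, drop = FALSE]
      ep_loss <- ep_loss + cross_entropy(cache$probs, Yb) * length(b)
      grads <- net_backward(params, ops, cache, Yb)
      upd <- adam_step(params, grads, state, hyper$lr)
      params <- upd$params
      state <- upd$state
    }
    ep_loss <- ep_loss / length(ord)
    val_loss <- NA_real_
    monitor <- ep_loss
    if (length(val_idx)) {
      vp <- net_forward(params, ops, X[, val_idx, drop = FALSE])$probs
      val_loss <- cross_entropy(vp, Yall[, val_idx, drop = FALSE])
      monitor <- val_loss
    }
    log_epoch <- c(log_epoch, epoch)
    log_loss <- c(log_loss, ep_loss)
    log_val <- c(log_val, val_loss)
    if (monitor < best$loss - 1e-6) {
      best <- list(loss = monitor, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (ep_loss < hyper$loss_tol) break
    if (stall >= hyper$patience) break
  }
  structure(
    list(params = best$params, arch = arch, ops = ops, seed = seed,
         hyper = hyper,
         log = tibble::tibble(epoch = log_epoch, loss = log_loss,
                              val_loss = log_val)),
    class = "trained_cnn"
  )
}

#' @export
print.trained_cnn <- function(x, ...) {
  cat(sprintf("<trained_cnn> %s, input %s, H=%d, %d epochs (seed %d)\n",
              x$arch$model_tag, paste(x$arch$input_shape, collapse = "x"),
              x$arch$H, nrow(x$log), x$seed))
  invisible(x)
}

#' Posterior class probabilities from a trained network
#'
#' Runs the forward pass and returns the softmax output, an estimate of the
#' posterior class probabilities (non-negative, summing to one).
#'
#' @param net A `trained_cnn`.
#' @param input One input (vector/matrix/array matching the architecture's
#'   input shape) or a feature matrix with one column per sample.
#' @return A length-H posterior vector for a single input, or an `H x n`
#'   matrix of posteriors for a batch.
#' @export
forward_posteriors <- function(net, input) {
  flat <- prod(net$arch$input_shape)
  single <- FALSE
  if (length(input) == flat && !identical(dim(input), c(flat, 1L))) {
    X <- matrix(as.numeric(input), ncol = 1)
    single <- TRUE
  } else if (is.matrix(input) && nrow(input) == flat) {
    X <- input
  } else {
    stop("input shape does not match the network architecture", call. = FALSE)
  }
  probs <- net_forward(net$params, net$ops, X)$probs
  if (single) drop(probs) else probs
}
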