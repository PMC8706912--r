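#' Build a CNN fusion-classifier architecture
#'
#' All four network models share the fixed layer stack
#' conv–conv–pool–FC(sigmoid)–FC(softmax) with 32 + 32 filters, "same"
#' convolutions (stride 1, zero padding `(f - 1) / 2` per axis) and max
#' pooling; they differ in the first-layer filter geometry, which follows
#' the input model:
#' \describe{
#'   \item{CNN1 (per-axis vectors)}{filters `1 x 3 x 1`, then `1 x 3 x 32`;
#'     pooling `1 x 2`, stride 2;}
#'   \item{CNN2 (per-sensor matrices)}{`3 x 3 x 1`, then `3 x 3 x 32`;
#'     pooling `2 x 2`, stride 2;}
#'   \item{CNN3 (global matrix)}{`3 x 3 x 1`, then `3 x 3 x 32`; pooling
#'     `2 x 2`, stride 2;}
#'   \item{CNN4 (cuboid)}{depth-spanning filters `3 x 3 x G`, then
#'     `3 x 3 x 32` — convolving two cuboids of equal depth yields a matrix;
#'     pooling `2 x 2`, stride 2.}
#' }
#' Pooling windows are clipped to the available spatial extent; pooled
#' dimensions use floor division when sizes do not divide evenly.
#'
#' @param model_tag `"cnn1"`, `"cnn2"`, `"cnn3"` or `"cnn4"`.
#' @param input_shape Integer `(height, width, depth)` of one input: a
#'   length-n channel is `(1, n, 1)`, an `m x n` matrix `(m, n, 1)`, an
#'   `M x N x G` cuboid `(M, N, G)`.
#' @param H Number of movement classes (softmax width).
#' @param n_filters Filters per convolution layer (default `c(32, 32)`).
#' @param fc_width Hidden fully-connected width (default 100).
#' @param pool_stride Pooling stride (default 2).
#' @return A `cnn_architecture` with the full dimension chain.
#' @export
build_architecture <- function(model_tag, input_shape, H,
                               n_filters = c(32L, 32L), fc_width = 100L,
                               pool_stride = 2L) {
  model_tag <- tolower(model_tag)
  model_tag <- match.arg(model_tag, c("cnn1", "cnn2", "cnn3", "cnn4"))
  input_shape <- as.integer(rep_len(c(input_shape, 1L, 1L)[seq_len(3)], 3))
  d0 <- input_shape
  if (model_tag == "cnn1" && d0[1] != 1L) {
    stop("cnn1 expects vector inputs of shape (1, n, 1)", call. = FALSE)
  }
  if (model_tag != "cnn4" && d0[3] != 1L) {
    stop(sprintf("%s expects depth-1 inputs", model_tag), call. = FALSE)
  }
  fh <- if (model_tag == "cnn1") 1L else 3L
  filters <- list(c(fh, 3L, d0[3]), c(fh, 3L, n_filters[1]))
  pad <- lapply(filters, function(f) c((f[1] - 1L) %/% 2L, (3L - 1L) %/% 2L))
  d1 <- conv_output_dims(d0, filters[[1]], n_filters[1], pad[[1]], 1L)
  d2 <- conv_output_dims(d1, filters[[2]], n_filters[2], pad[[2]], 1L)
  pool_size <- if (model_tag == "cnn1") c(1L, 2L) else c(2L, 2L)
  pool_size <- pmin(pool_size, d2[1:2])
  dp <- pool_output_dims(d2, pool_size, pool_stride)
  structure(
    list(model_tag = model_tag, input_shape = d0, H = as.integer(H),
         n_filters = as.integer(n_filters), filters = filters, pad = pad,
         pool_size = as.integer(pool_size), pool_stride = as.integer(pool_stride),
         fc_width = as.integer(fc_width),
         dims = list(input = d0, conv1 = d1, conv2 = d2, pool = dp),
         flat_len = prod(dp)),
    class = "cnn_architecture"
  )
}

#' @export
print.cnn_architecture <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "<cnn_architecture> %s: %s -> conv%s -> conv%s -> pool%s -> FC(%d, sigmoid) -> FC(%d, softmax)\n",
    x$model_tag, paste(d$input, collapse = "x"), paste(d$conv1, collapse = "x"),
    paste(d$conv2, collapse = "x"), paste(d$pool, collapse = "x"),
    x$fc_width, x$H))
  invisible(x)
}

# Per-net training matrices for each input model. Returns a list of units,
# each with an id, an input shape, and a (features x n) matrix builder.
cnn_unit_inputs <- function(recs, model_tag, spec) {
  switch(model_tag,
    cnn1 = {
      chans <- sprintf("s%d.%d", spec$channel_len$sensor, spec$channel_len$axis)
      lens <- spec$channel_len$len
      lapply(seq_along(chans), function(k) {
        L <- lens[k]
        X <- vapply(recs, function(r) {
          fi <- build_input(r, "VI", spec)
          duration_normalize(fi$payload[[chans[k]]], L)
        }, numeric(L))
        list(id = chans[k], shape = c(1L, L, 1L),
             X = matrix(X, nrow = L))
      })
    },
    cnn2 = {
      lapply(seq_len(spec$G), function(g) {
        first <- build_input(recs[[1]], "LMI", spec)$payload[[g]]
        flat <- length(first)
        X <- vapply(recs, function(r) {
          as.numeric(build_input(r, "LMI", spec)$payload[[g]])
        }, numeric(flat))
        list(id = sprintf("sensor%d", g), shape = c(dim(first), 1L),
             X = matrix(X, nrow = flat))
      })
    },
    cnn3 = {
      first <- build_input(recs[[1]], "GMI", spec)$payload
      flat <- length(first)
      X <- vapply(recs, function(r) {
        as.numeric(build_input(r, "GMI", spec)$payload)
      }, numeric(flat))
      list(list(id = "global", shape = c(dim(first), 1L),
                X = matrix(X, nrow = flat)))
    },
    cnn4 = {
      first <- build_input(recs[[1]], "GCI", spec)$payload
      flat <- length(first)
      X <- vapply(recs, function(r) {
        as.numeric(build_input(r, "GCI", spec)$payload)
      }, numeric(flat))
      list(list(id = "cuboid", shape = dim(first), X = matrix(X, nrow = flat)))
    }
  )
}

#' Train a CNN fusion classifier
#'
#' Trains the per-unit networks of one of the four CNN fusion models: one
#' net per channel (CNN-1, `M_G` nets), one per sensor (CNN-2, `G` nets),
#' or a single net on the global matrix (CNN-3) or cuboid (CNN-4). Each
#' net's seed is derived from the master seed plus its unit index and
#' recorded in its training log.
#'
#' @param train List of labelled [movement_recording()]s; at least two
#'   classes, every class represented.
#' @param model_tag `"cnn1"`..`"cnn4"`.
#' @param spec A fitted `normalization_spec` for the matching input model.
#' @param hyper Training hyperparameters, see [train_cnn()].
#' @param seed Master integer seed.
#' @param H Number of classes; defaults to the maximum observed label.
#' @return A `cnn_fusion_fit` holding the trained nets.
#' @export
train_model <- function(train, model_tag, spec, hyper = list(), seed = 1L,
                        H = NULL) {
  model_tag <- tolower(model_tag)
  model_tag <- match.arg(model_tag, c("cnn1", "cnn2", "cnn3", "cnn4"))
  labels <- vapply(train, function(r) {
    if (is.null(r$label)) stop("all training recordings must be labelled", call. = FALSE)
    r$label
  }, integer(1))
  if (is.null(H)) H <- max(labels)
  if (H < 2L) stop("need at least two classes", call. = FALSE)
  missing <- setdiff(seq_len(H), unique(labels))
  if (length(missing)) {
    stop("no training recordings for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  units <- cnn_unit_inputs(train, model_tag, spec)
  nets <- lapply(seq_along(units), function(k) {
    u <- units[[k]]
    arch <- build_architecture(model_tag, u$shape, H)
    net <- train_cnn(u$X, labels, arch, hyper = hyper, seed = seed + k)
    net$unit <- u$id
    net
  })
  structure(
    list(model_tag = model_tag, nets = nets, spec = spec, H = as.integer(H),
         hyper = default_hyper(hyper), seed = as.integer(seed)),
    class = "cnn_fusion_fit"
  )
}

#' @export
print.cnn_fusion_fit <- function(x, ...) {
  cat(sprintf("<cnn_fusion_fit> %s: %d net(s), H=%d, master seed %d\n",
              x$model_tag, length(x$nets), x$H, x$seed))
  invisible(x)
}

#' Average per-unit posteriors into the fused posterior vector
#'
#' Output-level probability fusion: the element-wise arithmetic mean of the
#' per-channel (CNN-1) or per-sensor (CNN-2) posterior vectors. A single
#' vector (CNN-3/CNN-4) passes through unchanged. Averages of probability
#' vectors again sum to one.
#'
#' @param posteriors List of equal-length posterior vectors (or H x n
#'   matrices).
#' @return The fused posterior vector (or matrix).
#' @export
fuse_posteriors <- function(posteriors) {
  if (!length(posteriors)) stop("no posteriors to fuse", call. = FALSE)
  lens <- vapply(posteriors, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("posterior vectors must all have the same length", call. = FALSE)
  }
  Reduce(`+`, posteriors) / length(posteriors)
}

#' Maximum-response decision rule
#'
#' Assigns the movement to the class with the largest fused posterior;
#' ties go to the lowest class index.
#'
#' @param P A posterior vector, or an H x n matrix of posteriors (one
#'   decision per column).
#' @return Integer class index (or vector of them).
#' @export
decide <- function(P) {
  if (is.matrix(P)) {
    apply(P, 2, which.max)
  } else {
    which.max(P)
  }
}

#' Classify recordings with a CNN fusion fit
#'
#' Builds the per-unit inputs for each recording, runs the forward passes,
#' fuses the per-unit posteriors and applies the maximum-response rule.
#'
#' @param fit A `cnn_fusion_fit` from [train_model()].
#' @param recs List of [movement_recording()]s.
#' @return A list with `class` (integer vector of decisions) and
#'   `posteriors` (H x n fused posterior matrix).
#' @export
cnn_classify <- function(fit, recs) {
  units <- cnn_unit_inputs(recs, fit$model_tag, fit$spec)
  per_unit <- lapply(seq_along(fit$nets), function(k) {
    forward_posteriors(fit$nets[[k]], units[[k]]$X)
  })
  per_unit <- lapply(per_unit, function(p) if (is.matrix(p)) p else matrix(p, ncol = 1))
  fused <- fuse_posteriors(per_unit)
  list(class = as.integer(decide(fused)), posteriors = fused)
}
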