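#' Central-tendency estimate of a sample
#'
#' Estimators available for per-time-point template averaging. `alpha` is
#' the per-tail trimming / winsorizing fraction; the trimean is
#' `(Q1 + 2*Q2 + Q3) / 4`.
#'
#' @param x Numeric vector.
#' @param estimator One of `"mean"`, `"median"`, `"trimmed_mean"`,
#'   `"winsorized_mean"`, `"trimean"`.
#' @param alpha Tail fraction for the trimmed and winsorized means.
#' @return A single number.
#' @export
ct_estimate <- function(x, estimator = c("mean", "median", "trimmed_mean",
                                         "winsorized_mean", "trimean"),
                        alpha = 0.1) {
  estimator <- match.arg(estimator)
  switch(estimator,
    mean = mean(x),
    median = stats::median(x),
    trimmed_mean = mean(x, trim = alpha),
    winsorized_mean = {
      q <- stats::quantile(x, c(alpha, 1 - alpha), names = FALSE, type = 7)
      mean(pmin(pmax(x, q[1]), q[2]))
    },
    trimean = {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      (q[1] + 2 * q[2] + q[3]) / 4
    }
  )
}

# Column-wise central tendency of a stack of equal-length rows.
ct_columns <- function(rows, estimator, alpha) {
  apply(rows, 2, ct_estimate, estimator = estimator, alpha = alpha)
}

#' Estimate per-class reference templates
#'
#' Builds one reference template per movement class by element-wise
#' central-tendency estimation over that class's training recordings, after
#' duration normalization so that per-time-point averaging is well defined:
#' per-channel vectors for the VI model (each channel normalized to its own
#' training-mean length), per-sensor matrices for LMI, one global matrix for
#' GMI.
#'
#' @param train List of labelled [movement_recording()]s covering classes
#'   `1..H`.
#' @param model_tag `"VI"`, `"LMI"` or `"GMI"` (the cuboid model is not used
#'   with DTW: its alignment is identical to the global-matrix alignment).
#' @param spec A fitted `normalization_spec` for the same model.
#' @param estimator,alpha See [ct_estimate()].
#' @param H Number of classes; defaults to the maximum observed label.
#' @return An object of class `movement_templates`.
#' @export
fit_templates <- function(train, model_tag = spec$model_tag, spec,
                          estimator = "mean", alpha = 0.1, H = NULL) {
  model_tag <- match.arg(model_tag, c("VI", "LMI", "GMI"))
  labels <- vapply(train, function(r) {
    if (is.null(r$label)) stop("all training recordings must be labelled", call. = FALSE)
    r$label
  }, integer(1))
  if (is.null(H)) H <- max(labels)
  missing <- setdiff(seq_len(H), unique(labels))
  if (length(missing)) {
    stop("no training recordings for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  chan_targets <- stats::setNames(
    spec$channel_len$len,
    sprintf("s%d.%d", spec$channel_len$sensor, spec$channel_len$axis))
  templates <- lapply(seq_len(H), function(h) {
    recs <- train[labels == h]
    switch(model_tag,
      VI = {
        inputs <- lapply(recs, build_input, model_tag = "VI", spec = spec)
        chans <- names(inputs[[1]]$payload)
        out <- lapply(chans, function(ch) {
          L <- chan_targets[[ch]]
          rows <- do.call(rbind, lapply(inputs, function(fi) {
            duration_normalize(fi$payload[[ch]], L)
          }))
          ct_columns(rows, estimator, alpha)
        })
        stats::setNames(out, chans)
      },
      LMI = {
        inputs <- lapply(recs, build_input, model_tag = "LMI", spec = spec)
        lapply(seq_len(spec$G), function(g) {
          mats <- lapply(inputs, function(fi) fi$payload[[g]])
          elementwise_ct(mats, estimator, alpha)
        })
      },
      GMI = {
        mats <- lapply(recs, function(r) build_input(r, "GMI", spec)$payload)
        elementwise_ct(mats, estimator, alpha)
      }
    )
  })
  structure(
    list(model_tag = model_tag, estimator = estimator, alpha = alpha,
         spec = spec, H = H, templates = templates),
    class = "movement_templates"
  )
}

elementwise_ct <- function(mats, estimator, alpha) {
  if (estimator == "mean") {
    Reduce(`+`, mats) / length(mats)
  } else {
    arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
    apply(arr, c(1, 2), ct_estimate, estimator = estimator, alpha = alpha)
  }
}

#' @export
print.movement_templates <- function(x, ...) {
  cat(sprintf("<movement_templates> %s model, %d classes, estimator %s\n",
              x$model_tag, x$H, x$estimator))
  invisible(x)
}

new_prediction <- function(class, scores, rule) {
  structure(list(class = class, scores = scores, rule = rule),
            class = "movement_prediction")
}

#' @export
print.movement_prediction <- function(x, ...) {
  cat(sprintf("<movement_prediction> class %d (%s over %d classes)\n",
              x$class, x$rule, length(x$scores)))
  invisible(x)
}

argmin_tie_low <- function(x) which.min(x) # which.min returns the first minimum

#' DTW fusion classifiers
#'
#' The three dynamic-time-warping fusion classification models:
#' \describe{
#'   \item{`dtw1_classify` (VI model)}{one vector DTW per channel per class;
#'     the `M_G` per-channel discrepancies are averaged into the fused
#'     discrepancy `D_h`;}
#'   \item{`dtw2_classify` (LMI model)}{one matrix DTW per sensor per class;
#'     the `G` per-sensor discrepancies are averaged;}
#'   \item{`dtw3_classify` (GMI model)}{a single matrix DTW against each
#'     class's global template — no output fusion needed.}
#' }
#' All three assign the movement by the least-discrepancy rule
#' `argmin_h D_h`, ties going to the lowest class index.
#'
#' @param rec An unlabelled or labelled [movement_recording()] to classify.
#' @param templates A `movement_templates` fit from [fit_templates()] with
#'   the matching model tag.
#' @param metric DTW local cost metric.
#' @param objective DTW objective, see [dtw_align()].
#' @return A `movement_prediction`: list with `class` (the decision) and
#'   `scores` (the length-H fused discrepancy vector).
#' @export
dtw1_classify <- function(rec, templates, metric = "euclidean",
                          objective = "normalized") {
  stopifnot(templates$model_tag == "VI")
  fi <- build_input(rec, "VI", templates$spec)
  chans <- names(templates$templates[[1]])
  if (!all(chans %in% names(fi$payload))) {
    stop("recording channels do not match template channels", call. = FALSE)
  }
  scores <- vapply(seq_len(templates$H), function(h) {
    mean(vapply(chans, function(ch) {
      dtw_align(fi$payload[[ch]], templates$templates[[h]][[ch]],
                metric = metric, objective = objective)$value
    }, numeric(1)))
  }, numeric(1))
  new_prediction(argmin_tie_low(scores), scores, "least discrepancy")
}

#' @rdname dtw1_classify
#' @export
dtw2_classify <- function(rec, templates, metric = "euclidean",
                          objective = "normalized") {
  stopifnot(templates$model_tag == "LMI")
  fi <- build_input(rec, "LMI", templates$spec)
  G <- length(fi$payload)
  scores <- vapply(seq_len(templates$H), function(h) {
    mean(vapply(seq_len(G), function(g) {
      dtw_align(fi$payload[[g]], templates$templates[[h]][[g]],
                metric = metric, objective = objective)$value
    }, numeric(1)))
  }, numeric(1))
  new_prediction(argmin_tie_low(scores), scores, "least discrepancy")
}

#' @rdname dtw1_classify
#' @export
dtw3_classify <- function(rec, templates, metric = "euclidean",
                          objective = "normalized") {
  stopifnot(templates$model_tag == "GMI")
  fi <- build_input(rec, "GMI", templates$spec)
  scores <- vapply(seq_len(templates$H), function(h) {
    dtw_align(fi$payload, templates$templates[[h]],
              metric = metric, objective = objective)$value
  }, numeric(1))
  new_prediction(argmin_tie_low(scores), scores, "least discrepancy")
}
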