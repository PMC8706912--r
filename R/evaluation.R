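classifier_input_model <- function(model) {
  switch(model,
    dtw1 = , cnn1 = "VI",
    dtw2 = , cnn2 = "LMI",
    dtw3 = , cnn3 = "GMI",
    cnn4 = "GCI",
    stop("unknown classifier model: ", model, call. = FALSE)
  )
}

#' Fit one of the seven fusion classifiers
#'
#' Unified training entry point: fits the normalization spec on the
#' training set, then either the DTW class templates (`dtw1`..`dtw3`) or
#' the CNN nets (`cnn1`..`cnn4`) for the classifier's input model.
#'
#' @param train List of labelled [movement_recording()]s.
#' @param model One of `"dtw1"`, `"dtw2"`, `"dtw3"`, `"cnn1"`, `"cnn2"`,
#'   `"cnn3"`, `"cnn4"`.
#' @param amplitude_mode Passed to [fit_normalization()].
#' @param estimator,alpha Template estimator for the DTW models, see
#'   [ct_estimate()].
#' @param metric,objective DTW alignment settings, see [dtw_align()].
#' @param hyper CNN training settings, see [train_cnn()].
#' @param seed Master seed (used by the CNN models).
#' @param H Number of classes; defaults to the maximum training label.
#' @return A `movement_classifier_fit`.
#' @export
fit_movement_classifier <- function(train,
                                    model = c("dtw1", "dtw2", "dtw3",
                                              "cnn1", "cnn2", "cnn3", "cnn4"),
                                    amplitude_mode = "none",
                                    estimator = "mean", alpha = 0.1,
                                    metric = "euclidean",
                                    objective = "normalized",
                                    hyper = list(), seed = 1L, H = NULL) {
  model <- match.arg(model)
  input_model <- classifier_input_model(model)
  spec <- fit_normalization(train, input_model, amplitude_mode)
  engine <- if (startsWith(model, "dtw")) {
    fit_templates(train, input_model, spec, estimator = estimator,
                  alpha = alpha, H = H)
  } else {
    train_model(train, model, spec, hyper = hyper, seed = seed, H = H)
  }
  structure(
    list(model = model, input_model = input_model, engine = engine,
         spec = spec, metric = metric, objective = objective,
         H = engine$H, seed = as.integer(seed)),
    class = "movement_classifier_fit"
  )
}

#' @export
print.movement_classifier_fit <- function(x, ...) {
  cat(sprintf("<movement_classifier_fit> %s (%s input model), H=%d\n",
              x$model, x$input_model, x$H))
  invisible(x)
}

#' Classify recordings with a fitted fusion classifier
#'
#' @param object A `movement_classifier_fit`.
#' @param newdata List of [movement_recording()]s.
#' @param ... Unused.
#' @return A tibble with one row per recording: `.id`, `.pred_class`,
#'   `.truth` (NA when unlabelled) and one `score_h` column per class
#'   (fused discrepancies for DTW models, fused posteriors for CNN models).
#' @export
predict.movement_classifier_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "movement_recording")) newdata <- list(newdata)
  truth <- vapply(newdata, function(r) {
    if (is.null(r$label)) NA_integer_ else r$label
  }, integer(1))
  if (startsWith(object$model, "dtw")) {
    fun <- switch(object$model, dtw1 = dtw1_classify, dtw2 = dtw2_classify,
                  dtw3 = dtw3_classify)
    preds <- lapply(newdata, fun, templates = object$engine,
                    metric = object$metric, objective = object$objective)
    cls <- vapply(preds, `[[`, integer(1), "class")
    scores <- do.call(rbind, lapply(preds, `[[`, "scores"))
  } else {
    res <- cnn_classify(object$engine, newdata)
    cls <- res$class
    scores <- t(res$posteriors)
  }
  colnames(scores) <- sprintf("score_%d", seq_len(object$H))
  dplyr::bind_cols(
    tibble::tibble(.id = seq_along(newdata), .pred_class = cls, .truth = truth),
    tibble::as_tibble(scores)
  )
}

stratified_split <- function(labels, train_frac) {
  idx_by_class <- split(seq_along(labels), labels)
  train_idx <- unlist(lapply(idx_by_class, function(ix) {
    if (length(ix) < 2L) {
      stop("every class needs at least 2 recordings to stratify a split",
           call. = FALSE)
    }
    n_tr <- max(1L, min(length(ix) - 1L, round(train_frac * length(ix))))
    sample(ix, n_tr)
  }), use.names = FALSE)
  list(train = sort(train_idx),
       test = sort(setdiff(seq_along(labels), train_idx)))
}

#' Repeated stratified-holdout evaluation
#'
#' The evaluation protocol: the ensemble is split at random into training
#' and test sets (stratified per class), the classifier is fitted on the
#' training set and scored on the test set, and the split is repeated;
#' accuracies across repetitions are averaged into the final estimate.
#' Per-repetition seeds derive from the master seed, so reports are exactly
#' reproducible.
#'
#' @param data List of labelled [movement_recording()]s.
#' @param model Classifier tag, see [fit_movement_classifier()].
#' @param reps Number of random partitions (the full protocol uses 100;
#'   smaller values trade precision of the estimate for runtime).
#' @param train_frac Training fraction of each split (default 0.8).
#' @param seed Master seed.
#' @param ... Passed on to [fit_movement_classifier()].
#' @return An `evaluation_report`: per-repetition accuracies, their mean
#'   (in %), the per-class confusion matrix summed over repetitions, the
#'   classifier tag and a config digest.
#' @export
repeated_holdout <- function(data, model, reps = 100L, train_frac = 0.8,
                             seed = 1L, ...) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must lie strictly between 0 and 1", call. = FALSE)
  }
  labels <- vapply(data, function(r) {
    if (is.null(r$label)) stop("evaluation data must be labelled", call. = FALSE)
    r$label
  }, integer(1))
  H <- max(labels)
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 1L, reps)
  acc <- numeric(reps)
  confusion <- matrix(0L, H, H,
                      dimnames = list(truth = seq_len(H), pred = seq_len(H)))
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    split <- stratified_split(labels, train_frac)
    fit <- fit_movement_classifier(data[split$train], model = model,
                                   seed = rep_seeds[r] %% 1000000L, H = H, ...)
    pred <- stats::predict(fit, data[split$test])
    acc[r] <- 100 * mean(pred$.pred_class == pred$.truth)
    for (k in seq_len(nrow(pred))) {
      confusion[pred$.truth[k], pred$.pred_class[k]] <-
        confusion[pred$.truth[k], pred$.pred_class[k]] + 1L
    }
  }
  structure(
    list(model = model, H = H, reps = as.integer(reps),
         train_frac = train_frac,
         seed = as.integer(seed),
         accuracy = tibble::tibble(rep = seq_len(reps), accuracy = acc),
         mean_accuracy = mean(acc), confusion = confusion,
         config_digest = data_digest(data)),
    class = "evaluation_report"
  )
}

# Stable fingerprint of an ensemble + its generating config (if attached).
data_digest <- function(data) {
  cfg <- attr(data, "config")
  key <- list(
    n = length(data),
    labels = vapply(data, function(r) r$label %||% NA_integer_, integer(1)),
    sums = round(vapply(data, function(r) {
      sum(vapply(r$signals, function(s) sum(s$samples), numeric(1)))
    }, numeric(1)), 6),
    config = if (is.null(cfg)) NULL else unclass(cfg)
  )
  rlang::hash(key)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: mean accuracy %.2f%% over %d repetition(s) (H=%d)\n",
              x$model, x$mean_accuracy, x$reps, x$H))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.evaluation_report <- function(x, ...) {
  dplyr::mutate(x$accuracy, model = x$model, .before = 1)
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    model = x$model, H = x$H, reps = x$reps,
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = stats::sd(x$accuracy$accuracy),
    n_test_decisions = sum(x$confusion)
  )
}

#' Uniaxial baseline accuracies
#'
#' Classifies every uniaxial channel independently with a single-channel
#' classifier of the requested family (vector-DTW nearest template, or a
#' per-axis CNN), using the same repeated-holdout protocol, and tabulates
#' the mean accuracies; the best axis is flagged (ties to the first).
#'
#' @param data List of labelled [movement_recording()]s.
#' @param family `"dtw"` or `"cnn"`.
#' @param reps,train_frac,seed See [repeated_holdout()].
#' @param ... Passed on to [fit_movement_classifier()].
#' @return A tibble with one row per (sensor, axis): `mean_accuracy` (%)
#'   and `best` flag; the per-channel `evaluation_report`s are attached as
#'   attribute `reports`, the ensemble digest as attribute `config_digest`.
#' @export
uniaxial_baseline <- function(data, family = c("dtw", "cnn"), reps = 10L,
                              train_frac = 0.8, seed = 1L, ...) {
  family <- match.arg(family)
  model <- if (family == "dtw") "dtw1" else "cnn1"
  G <- rec_G(data[[1]])
  m_g <- rec_mg(data[[1]])
  rows <- list()
  reports <- list()
  k <- 0L
  for (g in seq_len(G)) {
    for (m in seq_len(m_g[g])) {
      k <- k + 1L
      sub <- lapply(data, subset_channel, sensor = g, axis = m)
      rep_k <- repeated_holdout(sub, model = model, reps = reps,
                                train_frac = train_frac, seed = seed + k, ...)
      rows[[k]] <- tibble::tibble(sensor = g, axis = m, family = family,
                                  mean_accuracy = rep_k$mean_accuracy)
      reports[[sprintf("s%d.%d", g, m)]] <- rep_k
    }
  }
  out <- dplyr::bind_rows(rows)
  out$best <- seq_len(nrow(out)) == which.max(out$mean_accuracy)
  attr(out, "reports") <- reports
  attr(out, "config_digest") <- data_digest(data)
  out
}

#' Expected accuracy of random classification
#'
#' The chance level for an H-class problem, `100 / H` percent, reported to
#' one decimal.
#'
#' @param H Number of classes (>= 1).
#' @return Accuracy in percent, rounded to one decimal.
#' @export
random_baseline <- function(H) {
  if (length(H) != 1L || is.na(H) || H < 1) stop("H must be >= 1", call. = FALSE)
  round(100 / H, 1)
}

#' Compare fusion against uniaxial accuracies
#'
#' Tabulates, per classifier family, the worst fusion accuracy and the best
#' uniaxial accuracy and their difference. Reporting only — no claim is
#' asserted. All reports must come from the same ensemble (digests are
#' checked).
#'
#' @param fusion_reports Named list of `evaluation_report`s for fusion
#'   classifiers.
#' @param uniaxial_tables Named list (by family, `"dtw"`/`"cnn"`) of
#'   [uniaxial_baseline()] tables.
#' @return A tibble with columns `family`, `min_fusion`, `max_uniaxial`,
#'   `difference`.
#' @export
fusion_vs_uniaxial_summary <- function(fusion_reports, uniaxial_tables) {
  digests <- c(
    vapply(fusion_reports, `[[`, character(1), "config_digest"),
    vapply(uniaxial_tables, function(t) attr(t, "config_digest"), character(1))
  )
  if (length(unique(digests)) != 1L) {
    stop("reports were computed on different ensembles (config digest mismatch)",
         call. = FALSE)
  }
  fusion_tbl <- tibble::tibble(
    model = names(fusion_reports),
    family = ifelse(startsWith(names(fusion_reports), "dtw"), "dtw", "cnn"),
    accuracy = vapply(fusion_reports, `[[`, numeric(1), "mean_accuracy")
  )
  purrr::map_dfr(names(uniaxial_tables), function(fam) {
    fus <- fusion_tbl[fusion_tbl$family == fam, ]
    uni <- uniaxial_tables[[fam]]
    tibble::tibble(
      family = fam,
      min_fusion = min(fus$accuracy),
      max_uniaxial = max(uni$mean_accuracy),
      difference = min(fus$accuracy) - max(uni$mean_accuracy)
    )
  })
}
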