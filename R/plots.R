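#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the channels of a movement recording
#'
#' One panel per (sensor, axis) channel, value against time.
#'
#' @param object A [movement_recording()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.movement_recording <- function(object, ...) {
  d <- as_tibble(object) |>
    dplyr::mutate(channel = sprintf("sensor %d / axis %d", .data$sensor,
                                    .data$axis))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Per-repetition test accuracies with the mean marked, or the summed
#' confusion matrix.
#'
#' @param object An `evaluation_report` from [repeated_holdout()].
#' @param type `"accuracy"` (default) or `"confusion"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, type = c("accuracy", "confusion"),
                                       ...) {
  type <- match.arg(type)
  if (type == "accuracy") {
    ggplot2::ggplot(object$accuracy,
                    ggplot2::aes(x = .data$rep, y = .data$accuracy)) +
      ggplot2::geom_col(fill = "grey60") +
      ggplot2::geom_hline(yintercept = object$mean_accuracy,
                          linetype = "dashed") +
      ggplot2::labs(title = sprintf("%s: mean accuracy %.2f%%", object$model,
                                    object$mean_accuracy),
                    x = "repetition", y = "test accuracy (%)") +
      ggplot2::theme_minimal()
  } else {
    d <- as.data.frame(as.table(object$confusion))
    names(d) <- c("truth", "pred", "count")
    ggplot2::ggplot(d, ggplot2::aes(x = .data$pred, y = .data$truth,
                                    fill = .data$count)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
      ggplot2::labs(title = sprintf("%s confusion (summed over %d reps)",
                                    object$model, object$reps),
                    x = "predicted class", y = "true class") +
      ggplot2::theme_minimal()
  }
}

#' Plot CNN training curves
#'
#' Training (and validation, when present) cross-entropy loss per epoch for
#' every net of a CNN fusion fit.
#'
#' @param object A `cnn_fusion_fit` from [train_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnn_fusion_fit <- function(object, ...) {
  d <- purrr::map_dfr(object$nets, function(net) {
    dplyr::mutate(net$log, unit = net$unit)
  }) |>
    tidyr::pivot_longer(c("loss", "val_loss"), names_to = "which",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~unit, scales = "free_y") +
    ggplot2::labs(title = sprintf("%s training curves", object$model_tag),
                  x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}
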