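# broom-style tidiers and ggplot2 autoplot methods for the package's result
# types.

#' Tidy a cross-validation result
#'
#' @param x A `gi_crossval` from [crossval_accuracy()].
#' @param ... Unused.
#' @return Tibble with one row per fold: `fold`, `accuracy`.
#' @export
tidy.gi_crossval <- function(x, ...) {
  tibble(fold = seq_along(x$fold_accuracy), accuracy = x$fold_accuracy)
}

#' @rdname tidy.gi_crossval
#' @return `glance()` returns a one-row tibble: `accuracy`, `folds`, `n`.
#' @export
glance.gi_crossval <- function(x, ...) {
  tibble(accuracy = x$accuracy, folds = x$folds, n = x$n)
}

#' Tidy an mRMR ranking
#'
#' @param x A `mrmr_ranking` from [mrmr_rank()].
#' @param ... Unused.
#' @return Tibble with `rank`, `column` (original index) and `score`.
#' @export
tidy.mrmr_ranking <- function(x, ...) {
  tibble(rank = seq_along(x$ranked_idx), column = x$ranked_idx,
         score = x$scores)
}

#' Tidy pixel confusion counts
#'
#' @param x A [confusion_counts()] object.
#' @param ... Unused.
#' @return Long tibble with `quantity` (tp/fp/tn/fn) and `pixels`.
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble(quantity = c("tp", "fp", "tn", "fn"),
         pixels = c(x$tp, x$fp, x$tn, x$fn))
}

#' Plot a training history
#'
#' Loss and overlap metrics per epoch, faceted by quantity.
#'
#' @param object A `gi_history` tibble from [train_segmentation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gi_history <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[c("epoch", "loss", "val_loss",
                                                  "dice", "val_dice")],
                              -"epoch", names_to = "metric",
                              values_to = "value")
  long <- dplyr::filter(long, is.finite(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ gsub("^val_", "", metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation confusion matrix
#'
#' @param object A `gi_crossval` from [crossval_accuracy()].
#' @param ... Unused.
#' @return A ggplot heatmap of the pooled confusion matrix.
#' @export
autoplot.gi_crossval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "pred", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("%d-fold CV accuracy %.3f",
                                  object$folds, object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot per-image segmentation metrics
#'
#' @param object A `gi_mask_eval` from [evaluate_masks()].
#' @param ... Unused.
#' @return A ggplot boxplot of the per-image metric distributions.
#' @export
autoplot.gi_mask_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_image, -"image",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
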