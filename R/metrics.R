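# Pixel-level evaluation of binary masks: confusion counts and the derived
# accuracy / precision / recall / F1 / Dice / IoU metrics. Undefined ratios
# (zero denominators) surface as NA, never as silent zeroes.

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth Binary (0/1) arrays of identical shape.
#' @return A `confusion_counts` object with fields `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(matrix(1, 4, 4), matrix(1, 4, 4))  # tp = 16
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth))) {
    abort(sprintf("mask shapes differ: (%s) vs (%s)",
                  paste(dim(pred) %||% length(pred), collapse = ", "),
                  paste(dim(truth) %||% length(truth), collapse = ", ")))
  }
  p <- as.vector(pred); t <- as.vector(truth)
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1))) {
    abort("masks must contain only 0 and 1")
  }
  new_confusion(tp = sum(p == 1 & t == 1), fp = sum(p == 1 & t == 0),
                tn = sum(p == 0 & t == 0), fn = sum(p == 0 & t == 1))
}

new_confusion <- function(tp, fp, tn, fn) {
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 tn = as.numeric(tn), fn = as.numeric(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%g fp=%g tn=%g fn=%g (total %g)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Segmentation metrics from confusion counts
#'
#' Computes accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`, recall
#' `tp/(tp+fn)`, F1 `2tp/(2tp+fp+fn)`, Dice `2*prec*rec/(prec+rec)` and the
#' foreground intersection-over-union `tp/(tp+fp+fn)` (reported as `miou`).
#' F1 and Dice are algebraically identical whenever both precision and
#' recall are defined and their sum is positive. A metric whose denominator
#' is zero is reported as `NA` (undefined), never silently as 0.
#'
#' @param counts A [confusion_counts()] object.
#' @param two_class_miou Also report `miou_two_class`, the mean of foreground
#'   and background IoU, for comparability with class-averaged conventions.
#' @return A one-row tibble of metrics.
#' @examples
#' seg_metrics(confusion_counts(matrix(1, 2, 2), matrix(1, 2, 2)))
#' @export
seg_metrics <- function(counts, two_class_miou = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  prec <- ratio(tp, tp + fp)
  rec <- ratio(tp, tp + fn)
  dice <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  out <- tibble(
    acc = ratio(tp + tn, tp + tn + fp + fn),
    prec = prec,
    rec = rec,
    f1 = ratio(2 * tp, 2 * tp + fp + fn),
    dice = dice,
    miou = ratio(tp, tp + fp + fn)
  )
  if (two_class_miou) {
    bg <- ratio(tn, tn + fp + fn)
    out$miou_two_class <- mean(c(out$miou, bg))
  }
  out
}

#' Evaluate predicted masks against ground truth
#'
#' Computes per-image metrics and an aggregate row. Macro aggregation
#' (default) averages each metric over the images where it is defined; micro
#' aggregation pools pixel counts across images first.
#'
#' @param pred,truth Lists of binary masks, or `H x W x N` arrays.
#' @param aggregate `"macro"` or `"micro"`.
#' @param two_class_miou Passed to [seg_metrics()].
#' @return A list with `per_image` (tibble, one row per image) and `summary`
#'   (one-row tibble).
#' @export
evaluate_masks <- function(pred, truth, aggregate = c("macro", "micro"),
                           two_class_miou = FALSE) {
  aggregate <- match.arg(aggregate)
  pred <- mask_list(pred); truth <- mask_list(truth)
  if (length(pred) != length(truth)) {
    abort("pred and truth must hold the same number of masks")
  }
  counts <- purrr::map2(pred, truth, confusion_counts)
  per_image <- purrr::map_dfr(counts, seg_metrics, two_class_miou = two_class_miou)
  per_image <- dplyr::bind_cols(tibble(image = seq_along(counts)), per_image)
  summary <- if (aggregate == "micro") {
    pooled <- new_confusion(
      tp = sum(vapply(counts, `[[`, numeric(1), "tp")),
      fp = sum(vapply(counts, `[[`, numeric(1), "fp")),
      tn = sum(vapply(counts, `[[`, numeric(1), "tn")),
      fn = sum(vapply(counts, `[[`, numeric(1), "fn"))
    )
    seg_metrics(pooled, two_class_miou = two_class_miou)
  } else {
    dplyr::summarise(per_image[-1],
                     dplyr::across(dplyr::everything(),
                                   ~ mean(.x, na.rm = TRUE)))
  }
  structure(list(per_image = per_image, summary = summary,
                 aggregate = aggregate),
            class = "gi_mask_eval")
}

#' @export
print.gi_mask_eval <- function(x, ...) {
  cat(sprintf("<gi_mask_eval> %d image(s), %s aggregation\n",
              nrow(x$per_image), x$aggregate))
  format_metric_report(x$summary)
  invisible(x)
}

mask_list <- function(x) {
  if (is.list(x)) return(x)
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) return(list(x))
  if (length(d) == 3L) {
    return(lapply(seq_len(d[3]), function(k) x[, , k]))
  }
  if (length(d) == 4L) {
    return(lapply(seq_len(d[4]), function(k) x[, , 1, k]))
  }
  abort("masks must be matrices, H x W x N arrays, or lists of matrices")
}

#' Format a metric report as a fixed-precision table
#'
#' @param metrics One-row tibble from [seg_metrics()] or
#'   [evaluate_masks()]`$summary`.
#' @param digits Decimal places (default 4).
#' @return Character vector of formatted lines, invisibly; printed as a
#'   side-effect.
#' @export
format_metric_report <- function(metrics, digits = 4) {
  vals <- vapply(metrics, function(v) {
    if (is.na(v)) "undef" else formatC(v, digits = digits, format = "f")
  }, character(1))
  lines <- sprintf("%-16s %s", names(vals), vals)
  cat(lines, sep = "\n")
  invisible(lines)
}
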