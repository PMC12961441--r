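# Point-wise segmentation metrics: per-class TP/FP/FN counts and the derived
# IoU, precision, recall and F1, macro-averaged over classes that occur.

#' Per-class confusion counts
#'
#' True/false positives and false negatives per class from point-wise
#' predictions; points whose true label is the ignore label are excluded.
#'
#' @param pred_labels,true_labels equal-length integer vectors.
#' @param num_classes number of classes C, default 3.
#' @param ignore_label default -1.
#' @return a `confusion_counts` list with integer vectors `tp`, `fp`, `fn`
#'   (length C) and the full C x C confusion `matrix` (rows = truth).
#' @export
confusion_counts <- function(pred_labels, true_labels, num_classes = 3L,
                             ignore_label = -1L) {
  if (length(pred_labels) != length(true_labels))
    stop("prediction and truth vectors differ in length")
  keep <- true_labels != ignore_label
  p <- pred_labels[keep]; t <- true_labels[keep]
  cm <- matrix(0L, num_classes, num_classes,
               dimnames = list(truth = 0:(num_classes - 1L),
                               pred = 0:(num_classes - 1L)))
  if (length(t) > 0L) {
    tab <- table(factor(t, levels = 0:(num_classes - 1L)),
                 factor(p, levels = 0:(num_classes - 1L)))
    cm[] <- as.integer(tab)
  }
  tp <- diag(cm)
  structure(list(tp = tp, fp = colSums(cm) - tp, fn = rowSums(cm) - tp,
                 matrix = cm),
            class = "confusion_counts")
}

#' Segmentation metric report
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (harmonic mean)
#' and IoU `TP/(TP+FP+FN)`, plus their macro means. Classes absent from both
#' prediction and truth (`TP+FP+FN = 0`) are undefined (`NA`) and excluded
#' from the means; `P = R = 0` yields `F1 = 0`.
#'
#' @param counts a [confusion_counts()] result.
#' @return a `metric_report`: data.frame with one row per class plus a
#'   `"mean"` row; columns `class`, `precision`, `recall`, `f1`, `iou`
#'   (fractions in \[0, 1\]).
#' @export
metric_report <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  seen <- (tp + fp + fn) > 0L
  prec <- ifelse(tp + fp > 0L, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0L, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  iou <- ifelse(seen, tp / (tp + fp + fn), 0)
  prec[!seen] <- NA_real_; rec[!seen] <- NA_real_
  f1[!seen] <- NA_real_; iou[!seen] <- NA_real_
  df <- data.frame(class = names(tp) %||% as.character(seq_along(tp) - 1L),
                   precision = prec, recall = rec, f1 = f1, iou = iou,
                   stringsAsFactors = FALSE)
  means <- colMeans(df[seen, c("precision", "recall", "f1", "iou")], na.rm = TRUE)
  out <- rbind(df, data.frame(class = "mean", precision = means[1],
                              recall = means[2], f1 = means[3], iou = means[4]))
  rownames(out) <- NULL
  structure(out, class = c("metric_report", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate predicted against true labels
#'
#' Convenience wrapper: [confusion_counts()] followed by [metric_report()].
#'
#' @inheritParams confusion_counts
#' @return a [metric_report()].
#' @export
evaluate_labels <- function(pred_labels, true_labels, num_classes = 3L,
                            ignore_label = -1L) {
  metric_report(confusion_counts(pred_labels, true_labels, num_classes,
                                 ignore_label))
}

#' Mean IoU of a metric report
#' @param report a [metric_report()].
#' @return scalar macro mean IoU.
#' @export
mean_iou <- function(report) report$iou[report$class == "mean"]
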