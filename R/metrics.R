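# Evaluation metrics for multi-class cleavage-site prediction and the
# derived positive/negative binary task.
#
# A prediction set is a tibble with one row per pattern: `label` (true
# class), `pred` (predicted class) and optionally a `prob` matrix column
# holding the full softmax vector (needed for top-k). Classes are
# 0..n_classes-1 with 0 = negative.

as_prediction_set <- function(preds, n_classes) {
  stopifnot(all(c("label", "pred") %in% names(preds)))
  if (any(preds$label < 0L | preds$label >= n_classes) ||
      any(preds$pred < 0L | preds$pred >= n_classes)) {
    abort(sprintf("labels/predictions must lie in 0..%d", n_classes - 1L))
  }
  preds
}

#' Confusion matrix
#'
#' Rows index the true class, columns the predicted class.
#'
#' @param preds Prediction tibble with `label` and `pred`.
#' @param n_classes Total number of classes `s` (classes `0..s-1`).
#' @return An `n_classes x n_classes` integer matrix with dimnames
#'   `true`/`predicted`.
#' @export
confusion_matrix <- function(preds, n_classes) {
  preds <- as_prediction_set(preds, n_classes)
  lv <- 0:(n_classes - 1L)
  m <- table(
    true = factor(preds$label, levels = lv),
    predicted = factor(preds$pred, levels = lv)
  )
  matrix(as.integer(m), n_classes, n_classes,
         dimnames = list(true = lv, predicted = lv))
}

#' Top-k accuracy
#'
#' Fraction of patterns whose true class is among the `k` most probable
#' predicted classes. Ties in probability are broken toward the lower class
#' index. `k = 1` uses the `pred` column directly.
#'
#' @inheritParams confusion_matrix
#' @param k Number of top classes considered.
#' @return A fraction in `[0, 1]`.
#' @export
top_k_accuracy <- function(preds, k = 1L, n_classes = NULL) {
  if (is.null(n_classes)) {
    n_classes <- if (!is.null(preds[["prob"]])) ncol(preds[["prob"]]) else max(preds$label, preds$pred) + 1L
  }
  preds <- as_prediction_set(preds, n_classes)
  if (k < 1L || k > n_classes) abort(sprintf("k must be in 1..%d", n_classes))
  if (k == 1L) return(mean(preds$pred == preds$label))
  if (is.null(preds[["prob"]])) abort("top-k accuracy for k > 1 needs the 'prob' column")
  hits <- vapply(seq_len(nrow(preds)), function(i) {
    top <- order(-preds[["prob"]][i, ], seq_len(n_classes))[seq_len(k)] - 1L
    preds$label[[i]] %in% top
  }, logical(1))
  mean(hits)
}

class_f1 <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom == 0, 0, 2 * tp / denom)
  f1
}

#' Macro and weighted F1 scores
#'
#' Per-class `F1_c = 2 TP_c / (2 TP_c + FP_c + FN_c)`. The macro score
#' averages over all `n_classes` classes (a class absent from both labels
#' and predictions contributes 0); the weighted score weights each class by
#' its frequency among the true labels, so absent classes drop out.
#'
#' @inheritParams confusion_matrix
#' @return A single numeric value.
#' @export
macro_f1 <- function(preds, n_classes) {
  cm <- confusion_matrix(preds, n_classes)
  mean(class_f1(cm))
}

#' @rdname macro_f1
#' @export
weighted_f1 <- function(preds, n_classes) {
  cm <- confusion_matrix(preds, n_classes)
  w <- rowSums(cm) / sum(cm)
  sum(w * class_f1(cm))
}

#' Perfect match fraction and positional shift error
#'
#' Both are computed only over "true positives" in the positional sense:
#' patterns where both the true and the predicted class are nonzero
#' (`N_TP` of them). PMF is the fraction predicted at exactly the right
#' interval; PSE is the mean absolute interval shift `|pred - lbl|`.
#' When `N_TP = 0` both are returned as `NA` with an explanatory
#' `"reason"` attribute (never silently 0).
#'
#' @inheritParams confusion_matrix
#' @return A list with elements `pmf`, `pse` and `n_tp`.
#' @export
pmf_pse <- function(preds, n_classes = NULL) {
  if (is.null(n_classes)) n_classes <- max(preds$label, preds$pred) + 1L
  preds <- as_prediction_set(preds, n_classes)
  tp <- preds$pred != 0L & preds$label != 0L
  n_tp <- sum(tp)
  if (n_tp == 0L) {
    na <- structure(NA_real_, reason = "no samples with both pred and label nonzero")
    return(list(pmf = na, pse = na, n_tp = 0L))
  }
  list(
    pmf = mean(preds$pred[tp] == preds$label[tp]),
    pse = mean(abs(preds$pred[tp] - preds$label[tp])),
    n_tp = n_tp
  )
}

#' Collapse multi-class predictions to the binary task
#'
#' Class 0 is negative; any nonzero class is positive. Probability columns
#' are dropped.
#'
#' @inheritParams confusion_matrix
#' @return Tibble with logical columns `label` and `pred`
#'   (`TRUE` = positive).
#' @export
binarize <- function(preds) {
  tibble::tibble(label = preds$label != 0L, pred = preds$pred != 0L)
}

#' Binary classification metrics
#'
#' Accuracy, specificity, sensitivity and Matthews correlation coefficient
#' from the positive/negative collapse of the multi-class predictions.
#' A zero MCC denominator is reported as 0 with `mcc_undefined = TRUE`.
#'
#' @param binary Tibble from [binarize()] (logical `label`, `pred`).
#' @return A list with `acc`, `spe`, `sen`, `mcc`, `mcc_undefined`.
#' @export
binary_metrics <- function(binary) {
  tp <- sum(binary$pred & binary$label)
  tn <- sum(!binary$pred & !binary$label)
  fp <- sum(binary$pred & !binary$label)
  fn <- sum(!binary$pred & binary$label)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc_undef <- denom == 0
  list(
    acc = (tp + tn) / (tp + tn + fp + fn),
    spe = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    sen = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    mcc = if (mcc_undef) 0 else (tp * tn - fp * fn) / denom,
    mcc_undefined = mcc_undef
  )
}

#' Full evaluation report
#'
#' Computes every metric of the evaluation suite: top-1 and top-3 accuracy,
#' macro and weighted F1, PMF, PSE, the confusion matrix and the derived
#' binary metrics.
#'
#' @inheritParams confusion_matrix
#' @param top_k Additional top-k accuracy to report (default 3).
#' @return An object of class `dicer_evaluation`.
#' @export
evaluate_predictions <- function(preds, n_classes, top_k = 3L) {
  preds <- as_prediction_set(preds, n_classes)
  pp <- pmf_pse(preds, n_classes)
  topk <- if (!is.null(preds[["prob"]])) {
    top_k_accuracy(preds, k = min(top_k, n_classes), n_classes = n_classes)
  } else {
    NA_real_
  }
  structure(
    list(
      n = nrow(preds),
      n_classes = n_classes,
      top1 = top_k_accuracy(preds, 1L, n_classes),
      top3 = topk,
      macro_f1 = macro_f1(preds, n_classes),
      weighted_f1 = weighted_f1(preds, n_classes),
      pmf = pp$pmf,
      pse = pp$pse,
      n_tp = pp$n_tp,
      binary = binary_metrics(binarize(preds)),
      confusion = confusion_matrix(preds, n_classes)
    ),
    class = "dicer_evaluation"
  )
}

#' @export
print.dicer_evaluation <- function(x, ...) {
  cat(sprintf("<dicer_evaluation> %d patterns, %d classes\n", x$n, x$n_classes))
  cat(sprintf("  top-1 %.4f | top-3 %s | macro F1 %.4f | weighted F1 %.4f\n",
              x$top1, ifelse(is.na(x$top3), "NA", sprintf("%.4f", x$top3)),
              x$macro_f1, x$weighted_f1))
  cat(sprintf("  PMF %s | PSE %s (N_TP = %d)\n",
              ifelse(is.na(x$pmf), "NA", sprintf("%.4f", x$pmf)),
              ifelse(is.na(x$pse), "NA", sprintf("%.4f", x$pse)), x$n_tp))
  b <- x$binary
  cat(sprintf("  binary: acc %.4f | spe %s | sen %s | mcc %.4f\n",
              b$acc,
              ifelse(is.na(b$spe), "NA", sprintf("%.4f", b$spe)),
              ifelse(is.na(b$sen), "NA", sprintf("%.4f", b$sen)), b$mcc))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `dicer_evaluation`.
#' @param ... Unused.
#' @return A tibble with columns `metric`, `value`.
#' @export
tidy.dicer_evaluation <- function(x, ...) {
  tibble::tibble(
    metric = c("top1", "top3", "macro_f1", "weighted_f1", "pmf", "pse",
               "binary_acc", "binary_spe", "binary_sen", "binary_mcc"),
    value = c(x$top1, x$top3, x$macro_f1, x$weighted_f1, as.numeric(x$pmf),
              as.numeric(x$pse), x$binary$acc, x$binary$spe, x$binary$sen,
              x$binary$mcc)
  )
}

#' @export
glance.dicer_evaluation <- function(x, ...) {
  tidyr::pivot_wider(tidy(x), names_from = "metric", values_from = "value") |>
    dplyr::mutate(n = x$n, n_tp = x$n_tp)
}

#' Export a confusion matrix as CSV
#'
#' Writes one row per true class with a `true` id column and one column per
#' predicted class.
#'
#' @param x A `dicer_evaluation` or a confusion matrix.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_confusion_csv <- function(x, path) {
  cm <- if (inherits(x, "dicer_evaluation")) x$confusion else x
  df <- tibble::as_tibble(as.data.frame.matrix(cm), .name_repair = "minimal")
  names(df) <- paste0("pred_", colnames(cm))
  df <- dplyr::bind_cols(tibble::tibble(true = rownames(cm)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Confusion-matrix heatmap
#'
#' x-axis: predicted class; y-axis: true class (top row = class 0).
#'
#' @param object A `dicer_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dicer_evaluation <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::tibble(
    true = rep(rownames(cm), times = ncol(cm)),
    predicted = rep(colnames(cm), each = nrow(cm)),
    count = as.vector(cm)
  )
  lv <- rownames(cm)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$predicted, levels = lv),
    y = factor(.data$true, levels = rev(lv)),
    fill = .data$count
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "Predicted class", y = "True class", fill = "Count") +
    ggplot2::theme_minimal()
}
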