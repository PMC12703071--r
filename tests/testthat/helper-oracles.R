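# Independent brute-force metric oracle: everything is recomputed with
# plain loops straight from the definitions, sharing no code with the
# package implementation.

oracle_metrics <- function(labels, preds, n_classes) {
  n <- length(labels)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_len(n)) {
    cm[labels[i] + 1L, preds[i] + 1L] <- cm[labels[i] + 1L, preds[i] + 1L] + 1L
  }
  f1 <- numeric(n_classes)
  for (c in seq_len(n_classes)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    f1[c] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  w <- rowSums(cm) / n
  tp_idx <- which(labels != 0L & preds != 0L)
  pmf <- if (length(tp_idx) == 0) NA_real_ else mean(preds[tp_idx] == labels[tp_idx])
  pse <- if (length(tp_idx) == 0) NA_real_ else mean(abs(preds[tp_idx] - labels[tp_idx]))
  TP <- sum(labels != 0L & preds != 0L)
  TN <- sum(labels == 0L & preds == 0L)
  FP <- sum(labels == 0L & preds != 0L)
  FN <- sum(labels != 0L & preds == 0L)
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  list(
    confusion = cm,
    top1 = sum(labels == preds) / n,
    macro_f1 = sum(f1) / n_classes,
    weighted_f1 = sum(w * f1),
    pmf = pmf, pse = pse,
    acc = (TP + TN) / n,
    spe = if (TN + FP == 0) NA_real_ else TN / (TN + FP),
    sen = if (TP + FN == 0) NA_real_ else TP / (TP + FN),
    mcc = if (den == 0) 0 else (TP * TN - FP * FN) / den
  )
}

oracle_topk <- function(labels, probs, k) {
  hits <- 0L
  for (i in seq_along(labels)) {
    p <- probs[i, ]
    ord <- order(-p, seq_along(p))
    if ((labels[i] + 1L) %in% ord[seq_len(k)]) hits <- hits + 1L
  }
  hits / length(labels)
}

random_prediction_set <- function(n_classes) {
  n <- sample(3:60, 1)
  probs <- matrix(stats::rexp(n * n_classes), n)
  probs <- probs / rowSums(probs)
  # pred is the argmax of the probability row, as a model would emit it
  tibble::tibble(
    label = sample(0:(n_classes - 1L), n, replace = TRUE),
    pred = max.col(probs, ties.method = "first") - 1L,
    prob = probs
  )
}
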