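test_that("top-k accuracy handles exact matches, full k and ties", {
  preds <- tibble::tibble(label = c(0L, 1L, 2L), pred = c(0L, 1L, 2L),
                          prob = diag(3))
  expect_equal(top_k_accuracy(preds, 1L, 3L), 1)
  expect_equal(top_k_accuracy(preds, 3L, 3L), 1)

  p2 <- tibble::tibble(label = c(1L, 2L, 0L), pred = c(1L, 2L, 1L),
                       prob = matrix(1 / 3, 3, 3))
  expect_equal(top_k_accuracy(p2, 1L, 3L), 2 / 3, tolerance = 1e-12)
  expect_error(top_k_accuracy(p2, 9L, 3L), "k must be")
})

test_that("macro and weighted F1 match hand-computed per-class scores", {
  preds <- tibble::tibble(label = c(1L, 1L, 0L, 0L), pred = c(1L, 0L, 0L, 0L))
  # class 1: TP 1, FP 0, FN 1 -> 2/3; class 0: TP 2, FP 1, FN 0 -> 4/5
  expect_equal(macro_f1(preds, 2L), (2 / 3 + 4 / 5) / 2, tolerance = 1e-12)
  expect_equal(weighted_f1(preds, 2L), 0.5 * 2 / 3 + 0.5 * 4 / 5,
               tolerance = 1e-12)

  perfect <- tibble::tibble(label = 0:3, pred = 0:3)
  expect_equal(macro_f1(perfect, 4L), 1)
  expect_equal(weighted_f1(perfect, 4L), 1)

  # all predictions collapse to one class over uniform labels: the macro
  # average divides that single nonzero F1 by the class count
  collapse <- tibble::tibble(label = rep(0:3, each = 5), pred = rep(2L, 20))
  cm <- confusion_matrix(collapse, 4L)
  f1_2 <- 2 * cm[3, 3] / (2 * cm[3, 3] + (sum(cm[, 3]) - cm[3, 3]) +
                            (sum(cm[3, ]) - cm[3, 3]))
  expect_equal(macro_f1(collapse, 4L), f1_2 / 4, tolerance = 1e-12)
})

test_that("PMF and PSE are restricted to positional true positives", {
  preds <- tibble::tibble(label = c(3L, 4L, 2L), pred = c(3L, 5L, 0L))
  pp <- pmf_pse(preds, 14L)
  expect_equal(pp$n_tp, 2L)
  expect_equal(pp$pmf, 0.5)
  expect_equal(pp$pse, 0.5)

  exact <- tibble::tibble(label = c(1L, 5L), pred = c(1L, 5L))
  pp2 <- pmf_pse(exact, 14L)
  expect_equal(pp2$pmf, 1)
  expect_equal(pp2$pse, 0)

  shift <- tibble::tibble(label = 13L, pred = 1L)
  pp3 <- pmf_pse(shift, 14L)
  expect_equal(pp3$pmf, 0)
  expect_equal(pp3$pse, 12)

  none <- tibble::tibble(label = c(0L, 3L), pred = c(2L, 0L))
  pp4 <- pmf_pse(none, 14L)
  expect_true(is.na(pp4$pmf) && is.na(pp4$pse))
  expect_match(attr(pp4$pmf, "reason"), "nonzero")
})

test_that("binarization maps class 0 to negative and everything else to positive", {
  preds <- tibble::tibble(label = c(0L, 3L, 7L), pred = c(2L, 3L, 0L))
  b <- binarize(preds)
  expect_equal(b$label, c(FALSE, TRUE, TRUE))
  expect_equal(b$pred, c(TRUE, TRUE, FALSE))
  expect_equal(binarize(tibble::tibble(label = c(0L, 0L), pred = c(0L, 0L)))$pred,
               c(FALSE, FALSE))
  expect_identical(binarize(b |> dplyr::mutate(label = as.integer(label),
                                               pred = as.integer(pred))), b)
})

test_that("binary metrics follow the printed formulas", {
  mk <- function(tp, tn, fp, fn) {
    tibble::tibble(
      label = c(rep(TRUE, tp), rep(FALSE, tn), rep(FALSE, fp), rep(TRUE, fn)),
      pred = c(rep(TRUE, tp), rep(FALSE, tn), rep(TRUE, fp), rep(FALSE, fn))
    )
  }
  m <- binary_metrics(mk(2, 2, 0, 0))
  expect_equal(unlist(m[c("acc", "spe", "sen", "mcc")]),
               c(acc = 1, spe = 1, sen = 1, mcc = 1))
  m2 <- binary_metrics(mk(1, 1, 1, 1))
  expect_equal(m2$acc, 0.5)
  expect_equal(m2$mcc, 0)
  m3 <- binary_metrics(mk(3, 5, 1, 1))
  expect_equal(m3$acc, 0.8)
  expect_equal(m3$spe, 5 / 6, tolerance = 1e-12)
  expect_equal(m3$sen, 0.75)
  expect_equal(m3$mcc, 14 / 24, tolerance = 1e-12)
  # degenerate table: MCC denominator 0 reported as flagged 0
  m4 <- binary_metrics(mk(0, 0, 0, 2))
  expect_equal(m4$mcc, 0)
  expect_true(m4$mcc_undefined)
})

test_that("all metrics agree with the brute-force oracle on random prediction sets", {
  set.seed(17)
  for (i in 1:200) {
    n_classes <- sample(c(2L, 5L, 14L), 1)
    ps <- random_prediction_set(n_classes)
    o <- oracle_metrics(ps$label, ps$pred, n_classes)
    ev <- evaluate_predictions(ps, n_classes)
    expect_equal(unname(ev$confusion), o$confusion, ignore_attr = TRUE)
    expect_equal(ev$top1, o$top1, tolerance = 1e-12)
    expect_equal(ev$macro_f1, o$macro_f1, tolerance = 1e-12)
    expect_equal(ev$weighted_f1, o$weighted_f1, tolerance = 1e-12)
    expect_equal(as.numeric(ev$pmf), o$pmf, tolerance = 1e-12)
    expect_equal(as.numeric(ev$pse), o$pse, tolerance = 1e-12)
    expect_equal(ev$binary$acc, o$acc, tolerance = 1e-12)
    expect_equal(ev$binary$mcc, o$mcc, tolerance = 1e-12)
    k <- sample.int(n_classes, 1)
    expect_equal(top_k_accuracy(ps, k, n_classes),
                 oracle_topk(ps$label, ps$prob, k), tolerance = 1e-12)
    # structural invariants
    expect_equal(ev$top1, sum(diag(ev$confusion)) / nrow(ps), tolerance = 1e-12)
    if (!is.na(ev$pmf) && ev$n_tp > 0) {
      expect_equal(ev$pmf == 1, ev$pse == 0)
    }
  }
})

test_that("top-k accuracy is nondecreasing in k", {
  set.seed(23)
  ps <- random_prediction_set(14L)
  accs <- vapply(1:14, function(k) top_k_accuracy(ps, k, 14L), numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[14], 1)
})

test_that("evaluation reports tidy into long and wide tibbles", {
  preds <- tibble::tibble(label = c(0L, 1L, 2L, 1L), pred = c(0L, 1L, 1L, 1L),
                          prob = matrix(1 / 3, 4, 3))
  ev <- evaluate_predictions(preds, 3L)
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("top1", "pmf", "binary_mcc") %in% td$metric))
  gl <- glance(ev)
  expect_equal(gl$top1, ev$top1)
  expect_equal(gl$n, 4L)
  expect_s3_class(autoplot(ev), "ggplot")

  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(ev, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 3L)
  expect_equal(as.matrix(back[, -1]), unclass(ev$confusion), ignore_attr = TRUE)
})
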