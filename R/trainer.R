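# Fivefold cross-validation training with the study's optimisation
# protocol: AdamW (lr 1e-3, weight decay 1e-5), mini-batches of 128,
# per-epoch shuffling, plateau learning-rate halving on validation loss,
# early stopping on validation loss, and up-to-three best checkpoints
# ranked by validation top-1 accuracy.

#' Training configuration
#'
#' @param batch_size Mini-batch size.
#' @param lr Initial learning rate.
#' @param weight_decay Decoupled (AdamW) weight decay.
#' @param max_epochs Maximum training epochs.
#' @param scheduler_factor Multiplier applied to the learning rate when the
#'   validation loss plateaus.
#' @param scheduler_patience Epochs without validation-loss improvement
#'   before the learning rate is reduced.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before training stops.
#' @param val_fraction Fraction of the development split held out for
#'   validation.
#' @param checkpoint_selection `"validation"` scores the checkpoint with
#'   the best validation top-1 on the test fold once; `"test"` mimics the
#'   protocol of picking the checkpoint that scores best on the test fold
#'   (this leaks the test set into model selection and inflates test
#'   estimates — a warning is emitted).
#' @param n_best_checkpoints How many best-validation checkpoints to keep.
#' @param seed Integer seed controlling the train/validation split,
#'   shuffling and dropout.
#' @param verbose Print per-epoch progress lines.
#' @return A list of class `dicer_train_config`.
#' @export
dicer_train_config <- function(batch_size = 128L, lr = 1e-3,
                               weight_decay = 1e-5, max_epochs = 100L,
                               scheduler_factor = 0.5, scheduler_patience = 5L,
                               early_stop_patience = 10L, val_fraction = 0.1,
                               checkpoint_selection = c("validation", "test"),
                               n_best_checkpoints = 3L, seed = 1L,
                               verbose = FALSE) {
  checkpoint_selection <- match.arg(checkpoint_selection)
  if (scheduler_factor <= 0 || scheduler_factor >= 1) {
    abort("scheduler_factor must be in (0, 1)")
  }
  if (scheduler_patience < 1L || early_stop_patience < 1L) {
    abort("patience values must be >= 1")
  }
  structure(
    list(batch_size = as.integer(batch_size), lr = lr,
         weight_decay = weight_decay, max_epochs = as.integer(max_epochs),
         scheduler_factor = scheduler_factor,
         scheduler_patience = as.integer(scheduler_patience),
         early_stop_patience = as.integer(early_stop_patience),
         val_fraction = val_fraction,
         checkpoint_selection = checkpoint_selection,
         n_best_checkpoints = as.integer(n_best_checkpoints),
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "dicer_train_config"
  )
}

#' Desk-scale preset
#'
#' A CPU-friendly configuration pair for small corpora (a few thousand
#' patterns): the model keeps the published depth and model dimension but
#' uses narrower feed-forward/projection widths, and training runs at most
#' 15 epochs with short patiences.
#'
#' @param s Pattern size.
#' @param fusion Fusion strategy.
#' @param seed Integer seed.
#' @return A list with elements `model` ([dicer_model_config()]) and
#'   `train` ([dicer_train_config()]).
#' @export
small_preset <- function(s = 14L, fusion = "aff", seed = 1L) {
  list(
    model = dicer_model_config(s = s, ff_dim = 128L, out_dim = 128L,
                               fc_hidden = 64L, fusion = fusion),
    train = dicer_train_config(max_epochs = 15L, scheduler_patience = 2L,
                               early_stop_patience = 4L, seed = seed)
  )
}

# Plateau LR scheduling + early stopping on validation loss, kept as a
# small pure state machine so the mechanism is testable in isolation.
plateau_state <- function(lr, factor, scheduler_patience, early_stop_patience) {
  list(lr = lr, factor = factor,
       scheduler_patience = scheduler_patience,
       early_stop_patience = early_stop_patience,
       best = Inf, stale = 0L, lr_stale = 0L, stop = FALSE)
}

plateau_update <- function(state, val_loss) {
  if (val_loss < state$best - 1e-8) {
    state$best <- val_loss
    state$stale <- 0L
    state$lr_stale <- 0L
  } else {
    state$stale <- state$stale + 1L
    state$lr_stale <- state$lr_stale + 1L
    if (state$lr_stale >= state$scheduler_patience) {
      state$lr <- state$lr * state$factor
      state$lr_stale <- 0L
    }
    if (state$stale >= state$early_stop_patience) state$stop <- TRUE
  }
  state
}

eval_split <- function(model, enc, idx, batch_size) {
  batches <- split(idx, ceiling(seq_along(idx) / batch_size))
  total_loss <- 0
  n <- 0L
  probs <- matrix(NA_real_, length(idx), model$config$n_classes)
  at <- 0L
  for (b in batches) {
    fwd <- model_forward_batch(model, enc, b, training = FALSE)
    ce <- softmax_ce(fwd$logits, enc$label[b])
    total_loss <- total_loss + ce$loss * length(b)
    probs[at + seq_along(b), ] <- fwd$probs
    at <- at + length(b)
    n <- n + length(b)
  }
  pred <- max.col(probs, ties.method = "first") - 1L
  list(loss = total_loss / n, top1 = mean(pred == enc$label[idx]),
       probs = probs, pred = pred)
}

#' Train on one cross-validation fold
#'
#' The held-out fold is the test set; the remaining samples are split
#' 90/10 into training and validation (seeded). Training shuffles sample
#' order every epoch, halves the learning rate when the validation loss
#' fails to improve for `scheduler_patience` epochs, stops early after
#' `early_stop_patience` epochs without improvement, and keeps the final
#' model plus up to three checkpoints with the highest validation top-1
#' accuracy. The selected checkpoint is scored on the test fold exactly
#' once.
#'
#' @param dataset A `dicer_dataset` with folds assigned ([split_folds()]).
#' @param fold_id Which fold to hold out (0-based).
#' @param model_cfg A [dicer_model_config()]; its `s` must match the
#'   dataset.
#' @param train_cfg A [dicer_train_config()].
#' @return An object of class `dicer_fold` with the trained model, loss
#'   curves, the selected checkpoint's test predictions and its
#'   `dicer_evaluation` report.
#' @export
train_fold <- function(dataset, fold_id, model_cfg = dicer_model_config(),
                       train_cfg = dicer_train_config()) {
  if (!"fold" %in% names(dataset) || anyNA(dataset$fold)) {
    abort("dataset has no fold assignment; run split_folds() first")
  }
  if (!fold_id %in% unique(dataset$fold)) {
    abort(paste0("fold_id ", fold_id, " not present in dataset"))
  }
  s <- attr(dataset, "s") %||% unique(nchar(dataset$pattern_seq))[[1]]
  if (model_cfg$s != s) {
    abort(sprintf("model config s = %d but dataset pattern size is %d",
                  model_cfg$s, s))
  }
  model <- dicer_model(model_cfg, seed = train_cfg$seed)
  enc <- encode_dataset(dataset, model)

  test_idx <- which(dataset$fold == fold_id)
  dev_idx <- which(dataset$fold != fold_id)
  split_seed <- derive_seed(train_cfg$seed, "split")
  dev_idx <- with_seed(split_seed, sample(dev_idx))
  n_val <- max(1L, round(train_cfg$val_fraction * length(dev_idx)))
  val_idx <- dev_idx[seq_len(n_val)]
  train_idx <- dev_idx[-seq_len(n_val)]

  present <- sort(unique(enc$label[train_idx]))
  missing_classes <- setdiff(0:(model_cfg$n_classes - 1L), present)
  if (length(missing_classes) > 0) {
    warn(paste0("classes absent from the training split: ",
                paste(missing_classes, collapse = ", ")))
  }

  opt <- adamw_state(model$params)
  sched <- plateau_state(train_cfg$lr, train_cfg$scheduler_factor,
                         train_cfg$scheduler_patience,
                         train_cfg$early_stop_patience)
  history <- list()
  best_ckpts <- list()   # each: list(params, val_top1, val_loss, epoch)
  stopped_early <- FALSE

  set.seed(derive_seed(train_cfg$seed, "shuffle"))
  for (epoch in seq_len(train_cfg$max_epochs)) {
    order_idx <- sample(train_idx)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / train_cfg$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      fwd <- model_forward_batch(model, enc, b, training = TRUE)
      ce <- softmax_ce(fwd$logits, enc$label[b])
      grads <- model_backward_batch(model, fwd, ce$dlogits)
      step <- adamw_step(model$params, grads, opt, lr = sched$lr,
                         weight_decay = train_cfg$weight_decay)
      model$params <- step$params
      opt <- step$state
      epoch_loss <- epoch_loss + ce$loss * length(b)
    }
    epoch_loss <- epoch_loss / length(order_idx)
    val <- eval_split(model, enc, val_idx, train_cfg$batch_size)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = epoch_loss, val_loss = val$loss,
      val_top1 = val$top1, lr = sched$lr
    )
    if (train_cfg$verbose) {
      message(sprintf("epoch %3d | train loss %.4f | val loss %.4f | val top1 %.4f | lr %.2e",
                      epoch, epoch_loss, val$loss, val$top1, sched$lr))
    }

    # best-validation checkpoint pool (ranked by validation top-1)
    best_ckpts <- c(best_ckpts, list(list(
      params = model$params, val_top1 = val$top1, val_loss = val$loss,
      epoch = epoch
    )))
    ord <- order(-vapply(best_ckpts, `[[`, numeric(1), "val_top1"),
                 vapply(best_ckpts, `[[`, numeric(1), "epoch"))
    best_ckpts <- best_ckpts[ord[seq_len(min(length(best_ckpts),
                                             train_cfg$n_best_checkpoints))]]

    sched <- plateau_update(sched, val$loss)
    if (sched$stop) {
      stopped_early <- TRUE
      break
    }
  }
  history <- dplyr::bind_rows(history)
  final_params <- model$params

  candidates <- c(best_ckpts, list(list(params = final_params,
                                        val_top1 = NA_real_, val_loss = NA_real_,
                                        epoch = nrow(history))))
  if (train_cfg$checkpoint_selection == "validation") {
    selected <- best_ckpts[[1]]
  } else {
    warn("checkpoint_selection = 'test' scores every checkpoint on the test fold; test estimates are optimistically biased")
    test_scores <- vapply(candidates, function(ck) {
      model$params <- ck$params
      eval_split(model, enc, test_idx, train_cfg$batch_size)$top1
    }, numeric(1))
    selected <- candidates[[which.max(test_scores)]]
  }
  model$params <- selected$params
  test <- eval_split(model, enc, test_idx, train_cfg$batch_size)
  preds <- tibble::tibble(
    pattern_id = dataset$pattern_id[test_idx],
    label = enc$label[test_idx],
    pred = test$pred,
    prob = test$probs
  )
  report <- evaluate_predictions(preds, model_cfg$n_classes)
  structure(
    list(fold_id = fold_id, model = model, history = history,
         report = report, predictions = preds,
         selected_epoch = selected$epoch,
         best_checkpoints = lapply(best_ckpts, function(ck) {
           ck[c("val_top1", "val_loss", "epoch")]
         }),
         stopped_early = stopped_early, final_lr = sched$lr,
         train_idx = train_idx, val_idx = val_idx, test_idx = test_idx),
    class = "dicer_fold"
  )
}

#' @export
print.dicer_fold <- function(x, ...) {
  cat(sprintf("<dicer_fold> fold %d | %d epochs | test top-1 %.4f\n",
              x$fold_id, nrow(x$history), x$report$top1))
  invisible(x)
}

#' Loss-curve plot for one fold
#'
#' @param object A `dicer_fold`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dicer_fold <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Fivefold cross-validation
#'
#' Trains [train_fold()] on every fold and aggregates each metric as mean
#' and standard deviation across folds.
#'
#' @inheritParams train_fold
#' @param folds Which folds to run (default: all folds present).
#' @return An object of class `dicer_cv` with `folds` (list of
#'   `dicer_fold`) and `aggregate` (tibble of metric mean/sd).
#' @export
cross_validate <- function(dataset, model_cfg = dicer_model_config(),
                           train_cfg = dicer_train_config(),
                           folds = NULL) {
  if (is.null(folds)) folds <- sort(unique(dataset$fold))
  results <- purrr::map(folds, function(f) {
    train_fold(dataset, f, model_cfg, train_cfg)
  })
  agg <- aggregate_reports(purrr::map(results, "report"))
  structure(list(folds = results, aggregate = agg), class = "dicer_cv")
}

aggregate_reports <- function(reports) {
  per_fold <- purrr::imap_dfr(reports, function(r, i) {
    dplyr::mutate(tidy(r), fold = i - 1L)
  })
  per_fold |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      n_folds = sum(!is.na(.data$value)),
      .groups = "drop"
    )
}

#' @export
print.dicer_cv <- function(x, ...) {
  cat(sprintf("<dicer_cv> %d folds\n", length(x$folds)))
  print(x$aggregate, n = Inf)
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `dicer_cv`.
#' @param ... Unused.
#' @export
tidy.dicer_cv <- function(x, ...) {
  x$aggregate
}

#' @export
glance.dicer_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$aggregate[, c("metric", "mean")],
                             names_from = "metric", values_from = "mean")
  dplyr::mutate(wide, n_folds = length(x$folds))
}
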