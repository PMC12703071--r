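tiny_enc <- function(model, ds = fixture_tiny_dataset()) {
  dicersite:::encode_dataset(ds, model)
}

test_that("forward pass yields normalized probabilities and in-range classes", {
  m <- dicer_model(tiny_model_config(), seed = 2L)
  enc <- tiny_enc(m)
  fwd <- dicersite:::model_forward_batch(m, enc, 1:4)
  expect_equal(dim(fwd$probs), c(4L, 6L))
  expect_equal(unname(rowSums(fwd$probs)), rep(1, 4), tolerance = 1e-6)
  expect_true(all(max.col(fwd$probs) - 1L  %in% 0:5))
  expect_true(all(fwd$probs >= 0))
})

test_that("forward pass is deterministic given the init seed", {
  m1 <- dicer_model(tiny_model_config(), seed = 9L)
  m2 <- dicer_model(tiny_model_config(), seed = 9L)
  enc <- tiny_enc(m1)
  f1 <- dicersite:::model_forward_batch(m1, enc, 1:4)
  f2 <- dicersite:::model_forward_batch(m2, enc, 1:4)
  expect_identical(f1$logits, f2$logits)
})

test_that("encoder output is invariant to pad length", {
  m <- dicer_model(tiny_model_config(), seed = 4L)
  vs <- m$vocab_seq; vt <- m$vocab_struct
  ids_s <- list(dicersite:::encode_ids("ACGUACGUACC", "sequence", vs))
  ids_t <- list(dicersite:::encode_ids("(((.....)))", "structure", vt))
  s1 <- dicersite:::batch_stream(ids_s, ids_t, m$params, pad_to = 11L)
  s2 <- dicersite:::batch_stream(ids_s, ids_t, m$params, pad_to = 48L)
  e1 <- dicersite:::encoder_unit_fwd(s1, m$params, "seq", m$config)
  e2 <- dicersite:::encoder_unit_fwd(s2, m$params, "seq", m$config)
  expect_equal(e1$out, e2$out, tolerance = 1e-10)
})

test_that("model predictions are invariant to batch composition (masking contract)", {
  m <- dicer_model(tiny_model_config(), seed = 4L)
  ds <- fixture_tiny_dataset()
  # hairpins of different lengths force different pad lengths per batch
  p_all <- predict(m, ds, batch_size = 4L)
  p_one <- predict(m, ds, batch_size = 1L)
  expect_equal(p_all$prob, p_one$prob, tolerance = 1e-10)
})

test_that("attention weights from the channel attention block lie in (0, 1)", {
  m <- dicer_model(tiny_model_config(), seed = 6L)
  J <- matrix(rnorm(5 * 8), 5)
  w <- mscam(J, m)
  expect_equal(dim(w), dim(J))
  expect_true(all(w > 0 & w < 1))
  # zeroed bottlenecks give sigmoid(0) = 0.5 everywhere
  m0 <- m
  for (nm in grep("^aff\\.", names(m0$params), value = TRUE)) {
    m0$params[[nm]] <- m0$params[[nm]] * 0
  }
  expect_equal(mscam(J, m0), matrix(0.5, 5, 8), ignore_attr = TRUE)
})

test_that("attentional fusion obeys its equation limits", {
  m <- dicer_model(tiny_model_config(), seed = 8L)
  set.seed(1)
  X <- matrix(rnorm(3 * 8), 3)
  Y <- matrix(rnorm(3 * 8), 3)

  # saturate the attention block so w -> 1: fused output equals X
  m1 <- m
  for (nm in grep("^aff\\..*\\.W$", names(m1$params), value = TRUE)) {
    m1$params[[nm]] <- m1$params[[nm]] * 0
  }
  m1$params[["aff.g2.b"]] <- rep(40, 8)
  m1$params[["aff.l2.b"]] <- rep(0, 8)
  m1$params[["aff.g1.b"]] <- rep(0, 2)
  m1$params[["aff.l1.b"]] <- rep(0, 2)
  f1 <- aff_fuse(X, Y, m1)
  expect_equal(f1$Z, X, tolerance = 1e-12)

  # w -> 0: fused output equals Y
  m0 <- m1
  m0$params[["aff.g2.b"]] <- rep(-40, 8)
  f0 <- aff_fuse(X, Y, m0)
  expect_equal(f0$Z, Y, tolerance = 1e-12)

  # X == Y: a convex combination of equal points is that point
  fx <- aff_fuse(X, X, m)
  expect_equal(fx$Z, X, tolerance = 1e-12)
  expect_true(all(fx$w >= 0 & fx$w <= 1))
  expect_error(aff_fuse(X, Y[1:2, ], m), "equal shape")
})

test_that("concatenation fusion is order-sensitive and dimension-adding", {
  X <- matrix(1:6, 2)
  Y <- matrix(7:12, 2)
  Z <- concat_fuse(X, Y)
  expect_equal(dim(Z), c(2L, 6L))
  expect_equal(Z[, 1:3], X)
  expect_false(isTRUE(all.equal(concat_fuse(X, Y), concat_fuse(Y, X))))
})

test_that("top-k ranking breaks probability ties toward the lower class", {
  expect_equal(predict_topk(c(0.1, 0.7, 0.2), k = 1L), 1L)
  expect_equal(sort(predict_topk(c(0.1, 0.7, 0.2), k = 3L)), 0:2)
  p <- c(0, 0, 0.5, 0, 0, 0.5)
  expect_equal(predict_topk(p, k = 2L), c(2L, 5L))
  pm <- rbind(c(0.2, 0.3, 0.5), c(0.5, 0.3, 0.2))
  expect_equal(predict_topk(pm, k = 1L)[, 1], c(2L, 0L))
})

test_that("analytic gradients match finite differences on a down-scaled model", {
  for (fusion in c("aff", "concat")) {
    m <- dicer_model(tiny_model_config(fusion = fusion), seed = 3L)
    ds <- fixture_tiny_dataset()
    enc <- tiny_enc(m, ds)
    loss_fn <- function(model) {
      fwd <- dicersite:::model_forward_batch(model, enc, 1:4)
      dicersite:::softmax_ce(fwd$logits, enc$label[1:4])$loss
    }
    fwd <- dicersite:::model_forward_batch(m, enc, 1:4)
    ce <- dicersite:::softmax_ce(fwd$logits, enc$label[1:4])
    gr <- dicersite:::model_backward_batch(m, fwd, ce$dlogits)
    expect_setequal(names(gr), names(m$params))
    h <- 1e-5
    set.seed(31)
    for (nm in names(m$params)) {
      n <- length(m$params[[nm]])
      for (j in sample(n, min(2L, n))) {
        m2 <- m
        m2$params[[nm]][j] <- m2$params[[nm]][j] + h
        up <- loss_fn(m2)
        m2$params[[nm]][j] <- m2$params[[nm]][j] - 2 * h
        down <- loss_fn(m2)
        numeric_grad <- (up - down) / (2 * h)
        expect_equal(gr[[nm]][j], numeric_grad, tolerance = 1e-3)
      }
    }
  }
})

test_that("the network can overfit a tiny random dataset (capacity oracle)", {
  set.seed(77)
  n <- 32L
  s <- 6L
  letters4 <- c("A", "C", "G", "U")
  rand_str <- function(n, ab) paste0(sample(ab, n, replace = TRUE), collapse = "")
  tab <- tibble::tibble(
    pattern_id = paste0("r", seq_len(n)),
    premirna_id = paste0("h", seq_len(n)),
    window_start = 1L,
    pattern_seq = vapply(seq_len(n), function(i) rand_str(s, letters4), ""),
    pattern_struct = vapply(seq_len(n), function(i) rand_str(s, c("(", ")", ".")), ""),
    premirna_seq = vapply(seq_len(n), function(i) rand_str(20L, letters4), ""),
    premirna_struct = vapply(seq_len(n), function(i) rand_str(20L, c(".", "(", ")")), ""),
    label = sample(0:(s - 1L), n, replace = TRUE),
    fold = NA_integer_
  )
  ds <- dicersite:::new_pattern_dataset(tab, s = s, variant = "custom")
  m <- dicer_model(tiny_model_config(s = s), seed = 7L)
  enc <- tiny_enc(m, ds)
  opt <- dicersite:::adamw_state(m$params)
  loss <- NA_real_
  for (step in 1:200) {
    fwd <- dicersite:::model_forward_batch(m, enc, seq_len(n), training = FALSE)
    ce <- dicersite:::softmax_ce(fwd$logits, enc$label)
    loss <- ce$loss
    if (loss < 0.01) break
    gr <- dicersite:::model_backward_batch(m, fwd, ce$dlogits)
    st <- dicersite:::adamw_step(m$params, gr, opt, lr = 3e-3, weight_decay = 0)
    m$params <- st$params
    opt <- st$state
  }
  expect_lt(loss, 0.01)
  fwd <- dicersite:::model_forward_batch(m, enc, seq_len(n), training = FALSE)
  expect_equal(max.col(fwd$probs) - 1L, enc$label)
})

test_that("attention-weight diagnostics report one weight per sample in [0,1]", {
  m <- dicer_model(tiny_model_config(), seed = 12L)
  ds <- fixture_tiny_dataset()
  diag <- aff_weight_diagnostics(m, ds)
  expect_equal(nrow(diag$per_sample), nrow(ds))
  expect_true(all(diag$per_sample$mean_w >= 0 & diag$per_sample$mean_w <= 1))
  expect_named(diag$summary, c("mean", "min", "max"))

  mc <- dicer_model(tiny_model_config(fusion = "concat"), seed = 12L)
  expect_error(aff_weight_diagnostics(mc, ds), "AFF")
})

test_that("checkpoints round-trip a model bit-for-bit", {
  m <- dicer_model(tiny_model_config(), seed = 21L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  ds <- fixture_tiny_dataset()
  expect_identical(predict(m, ds)$prob, predict(back, ds)$prob)
})
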