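# The cleavage-site network: two Transformer-based encoder units (one for
# the cleavage pattern, one for the full hairpin), attentional feature
# fusion (AFF) or concatenation, and a fully connected softmax head over
# the s classes.

#' Model configuration
#'
#' Architecture published as layer counts and types: each encoder unit is
#' three standard Transformer encoder layers (multi-head self-attention +
#' feed-forward, post-norm), two convolutional blocks (1D conv + leaky
#' ReLU) with residual connections from the Transformer output to each
#' block, masked mean pooling over positions and a linear projection to a
#' fixed-dimensional feature. Widths not published are set here and
#' overridable.
#'
#' @param s Pattern size (number of classes).
#' @param embed_dim Token embedding dimension per stream component
#'   (sequence and structure each; the model dimension is `2 * embed_dim`).
#' @param n_layers Transformer encoder layers per unit.
#' @param n_heads Attention heads (`d_model` must be divisible).
#' @param ff_dim Feed-forward hidden width.
#' @param conv_kernel 1D convolution kernel (odd, same-padding).
#' @param out_dim Encoder-unit output (projection) dimension.
#' @param fc_hidden Hidden width of the classification head.
#' @param dropout Dropout fraction applied inside Transformer sublayers.
#' @param fusion `"aff"` or `"concat"`.
#' @param r MS-CAM bottleneck reduction ratio.
#' @param residual `"transformer"` wires both conv-block residuals from the
#'   Transformer output; `"chained"` wires block 2's residual from block
#'   1's output.
#' @param leaky_slope Negative slope of the leaky ReLU activations.
#' @param max_seq_len Maximum (padded) full-hairpin length accepted.
#' @return A list of class `dicer_model_config`.
#' @export
dicer_model_config <- function(s = 14L, embed_dim = 32L, n_layers = 3L,
                               n_heads = 4L, ff_dim = 256L, conv_kernel = 3L,
                               out_dim = 256L, fc_hidden = 128L, dropout = 0.1,
                               fusion = c("aff", "concat"), r = 4L,
                               residual = c("transformer", "chained"),
                               leaky_slope = 0.01, max_seq_len = 200L) {
  fusion <- match.arg(fusion)
  residual <- match.arg(residual)
  d_model <- 2L * as.integer(embed_dim)
  if (d_model %% n_heads != 0L) abort("d_model must be divisible by n_heads")
  if (conv_kernel %% 2L == 0L) abort("conv_kernel must be odd (same padding)")
  structure(
    list(
      s = as.integer(s), n_classes = as.integer(s),
      embed_dim = as.integer(embed_dim), d_model = d_model,
      n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
      ff_dim = as.integer(ff_dim), conv_kernel = as.integer(conv_kernel),
      out_dim = as.integer(out_dim), fc_hidden = as.integer(fc_hidden),
      dropout = dropout, fusion = fusion, r = as.integer(r),
      residual = residual, leaky_slope = leaky_slope,
      max_seq_len = as.integer(max_seq_len)
    ),
    class = "dicer_model_config"
  )
}

init_encoder_unit <- function(params, prefix, cfg) {
  D <- cfg$d_model
  for (l in seq_len(cfg$n_layers)) {
    lp <- sprintf("%s.l%d", prefix, l)
    for (nm in c("q", "k", "v", "o")) {
      params <- init_linear(params, paste0(lp, ".", nm), D, D)
    }
    params <- init_layernorm(params, paste0(lp, ".ln1"), D)
    params <- init_linear(params, paste0(lp, ".ff1"), D, cfg$ff_dim)
    params <- init_linear(params, paste0(lp, ".ff2"), cfg$ff_dim, D)
    params <- init_layernorm(params, paste0(lp, ".ln2"), D)
  }
  for (cb in 1:2) {
    params <- init_linear(params, sprintf("%s.conv%d", prefix, cb),
                          cfg$conv_kernel * D, D)
  }
  init_linear(params, paste0(prefix, ".proj"), D, cfg$out_dim)
}

#' Construct a cleavage-site model
#'
#' Builds the token vocabularies, initialises all parameters with fan-in
#' scaled uniform draws from `seed`, and returns an untrained model.
#'
#' @param config A [dicer_model_config()].
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `dicer_model`.
#' @export
dicer_model <- function(config = dicer_model_config(), seed = 1L) {
  vocab_seq <- build_vocab("sequence")
  vocab_struct <- build_vocab("structure")
  params <- with_seed(derive_seed(seed, "init"), {
    p <- list()
    p[["emb.seq"]] <- matrix(rnorm(vocab_seq$size * config$embed_dim),
                             vocab_seq$size, config$embed_dim)
    p[["emb.struct"]] <- matrix(rnorm(vocab_struct$size * config$embed_dim),
                                vocab_struct$size, config$embed_dim)
    p <- init_encoder_unit(p, "pat", config)
    p <- init_encoder_unit(p, "seq", config)
    if (config$fusion == "aff") {
      cr <- max(1L, config$out_dim %/% config$r)
      p <- init_linear(p, "aff.g1", config$out_dim, cr)
      p <- init_linear(p, "aff.g2", cr, config$out_dim)
      p <- init_linear(p, "aff.l1", config$out_dim, cr)
      p <- init_linear(p, "aff.l2", cr, config$out_dim)
      head_in <- config$out_dim
    } else {
      head_in <- 2L * config$out_dim
    }
    p <- init_linear(p, "head.fc1", head_in, config$fc_hidden)
    p <- init_linear(p, "head.fc2", config$fc_hidden, config$n_classes)
    p
  })
  structure(
    list(config = config, params = params,
         vocab_seq = vocab_seq, vocab_struct = vocab_struct, seed = seed),
    class = "dicer_model"
  )
}

#' @export
print.dicer_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cfg <- x$config
  cat(sprintf(
    "<dicer_model> %s fusion | s = %d | d_model = %d | %d layers x %d heads | %s parameters\n",
    cfg$fusion, cfg$s, cfg$d_model, cfg$n_layers, cfg$n_heads,
    format(n_par, big.mark = ",")
  ))
  invisible(x)
}

# --- batch assembly ------------------------------------------------------

# Tokenise a dataset once; returns a list of per-sample id vectors.
encode_dataset <- function(dataset, model) {
  list(
    pat_seq = purrr::map(dataset$pattern_seq, encode_ids,
                         kind = "sequence", vocab = model$vocab_seq),
    pat_struct = purrr::map(dataset$pattern_struct, encode_ids,
                            kind = "structure", vocab = model$vocab_struct),
    full_seq = purrr::map(dataset$premirna_seq, encode_ids,
                          kind = "sequence", vocab = model$vocab_seq),
    full_struct = purrr::map(dataset$premirna_struct, encode_ids,
                             kind = "structure", vocab = model$vocab_struct),
    label = as.integer(dataset$label),
    premirna_id = as.character(dataset$premirna_id)
  )
}

# Build the (B*P) x d_model stream matrix for a batch of id vectors.
# Returns values, mask, token ids aligned to valid rows (for the embedding
# backward scatter), B and P.
batch_stream <- function(seq_ids, struct_ids, params, pad_to = NULL) {
  B <- length(seq_ids)
  lens <- lengths(seq_ids)
  P <- if (is.null(pad_to)) max(lens) else as.integer(pad_to)
  if (any(lens > P)) abort("stream longer than pad length")
  d_emb <- ncol(params[["emb.seq"]])
  D <- 2L * d_emb
  X <- matrix(0, B * P, D)
  mask <- logical(B * P)
  pe <- sinusoidal_pe(P, D)
  rows_list <- vector("list", B)
  for (b in seq_len(B)) {
    n <- lens[[b]]
    rows <- (b - 1L) * P + seq_len(n)
    X[rows, seq_len(d_emb)] <- params[["emb.seq"]][seq_ids[[b]], , drop = FALSE]
    X[rows, d_emb + seq_len(d_emb)] <- params[["emb.struct"]][struct_ids[[b]], , drop = FALSE]
    X[rows, ] <- X[rows, ] + pe[seq_len(n), ]
    mask[rows] <- TRUE
    rows_list[[b]] <- rows
  }
  list(values = X, mask = mask, B = B, P = P,
       seq_ids = unlist(seq_ids), struct_ids = unlist(struct_ids),
       valid_rows = unlist(rows_list))
}

# --- encoder unit --------------------------------------------------------

encoder_unit_fwd <- function(stream, params, prefix, cfg, training = FALSE) {
  X <- stream$values
  mask <- stream$mask
  B <- stream$B; P <- stream$P
  if (!any(mask)) abort("all-pad input stream")
  caches <- list()
  X <- zero_pad_rows(X, mask)
  for (l in seq_len(cfg$n_layers)) {
    lp <- sprintf("%s.l%d", prefix, l)
    att <- mha_fwd(X, mask, B, P, params, lp, cfg$n_heads)
    dr1 <- dropout_fwd(att$out, cfg$dropout, training)
    ln1 <- layernorm_fwd(X + dr1$out, params, paste0(lp, ".ln1"))
    X1 <- zero_pad_rows(ln1$out, mask)
    ff1 <- linear_fwd(X1, params, paste0(lp, ".ff1"))
    act <- relu_fwd(ff1$out)
    ff2 <- linear_fwd(act$out, params, paste0(lp, ".ff2"))
    dr2 <- dropout_fwd(ff2$out, cfg$dropout, training)
    ln2 <- layernorm_fwd(X1 + dr2$out, params, paste0(lp, ".ln2"))
    Xout <- zero_pad_rows(ln2$out, mask)
    caches[[l]] <- list(att = att$cache, dr1 = dr1$cache, ln1 = ln1$cache,
                        ff1 = ff1$cache, act = act$cache, ff2 = ff2$cache,
                        dr2 = dr2$cache, ln2 = ln2$cache)
    X <- Xout
  }
  Tout <- X
  cv1 <- conv1d_fwd(Tout, B, P, params, paste0(prefix, ".conv1"), cfg$conv_kernel)
  lr1 <- leaky_relu_fwd(cv1$out, cfg$leaky_slope)
  B1 <- zero_pad_rows(lr1$out + Tout, mask)
  res2 <- if (cfg$residual == "transformer") Tout else B1
  cv2 <- conv1d_fwd(B1, B, P, params, paste0(prefix, ".conv2"), cfg$conv_kernel)
  lr2 <- leaky_relu_fwd(cv2$out, cfg$leaky_slope)
  B2 <- zero_pad_rows(lr2$out + res2, mask)
  pool <- masked_mean_fwd(B2, mask, B, P)
  proj <- linear_fwd(pool$out, params, paste0(prefix, ".proj"))
  list(
    out = proj$out,
    cache = list(layers = caches, cv1 = cv1$cache, lr1 = lr1$cache,
                 cv2 = cv2$cache, lr2 = lr2$cache, pool = pool$cache,
                 proj = proj$cache, mask = mask, prefix = prefix)
  )
}

encoder_unit_bwd <- function(dOut, cache, params, gr, cfg) {
  mask <- cache$mask
  dPool <- linear_bwd(dOut, cache$proj, params, gr)
  dB2 <- masked_mean_bwd(dPool, cache$pool)
  dB2 <- zero_pad_rows(dB2, mask)
  dLr2 <- leaky_relu_bwd(dB2, cache$lr2)
  dB1 <- conv1d_bwd(dLr2, cache$cv2, params, gr)
  dT <- 0
  if (cfg$residual == "transformer") dT <- dT + dB2 else dB1 <- dB1 + dB2
  dB1 <- zero_pad_rows(dB1, mask)
  dLr1 <- leaky_relu_bwd(dB1, cache$lr1)
  dT <- dT + conv1d_bwd(dLr1, cache$cv1, params, gr) + dB1
  dX <- zero_pad_rows(dT, mask)
  for (l in rev(seq_along(cache$layers))) {
    cl <- cache$layers[[l]]
    dLn2 <- zero_pad_rows(dX, mask)
    dSum2 <- layernorm_bwd(dLn2, cl$ln2, params, gr)
    dFf2 <- dropout_bwd(dSum2, cl$dr2)
    dAct <- linear_bwd(dFf2, cl$ff2, params, gr)
    dFf1 <- relu_bwd(dAct, cl$act)
    dX1 <- dSum2 + linear_bwd(dFf1, cl$ff1, params, gr)
    dX1 <- zero_pad_rows(dX1, mask)
    dSum1 <- layernorm_bwd(dX1, cl$ln1, params, gr)
    dAtt <- dropout_bwd(dSum1, cl$dr1)
    dX <- dSum1 + mha_bwd(dAtt, cl$att, params, gr)
    dX <- zero_pad_rows(dX, mask)
  }
  dX
}

# --- fusion --------------------------------------------------------------

mscam_fwd <- function(J, params) {
  C <- ncol(J)
  m <- rowMeans(J)
  Gin <- matrix(m, nrow(J), C)
  g1 <- linear_fwd(Gin, params, "aff.g1")
  ga <- relu_fwd(g1$out)
  g2 <- linear_fwd(ga$out, params, "aff.g2")
  l1 <- linear_fwd(J, params, "aff.l1")
  la <- relu_fwd(l1$out)
  l2 <- linear_fwd(la$out, params, "aff.l2")
  pre <- g2$out + l2$out
  w <- sigmoid(pre)
  list(out = w, cache = list(g1 = g1$cache, ga = ga$cache, g2 = g2$cache,
                             l1 = l1$cache, la = la$cache, l2 = l2$cache,
                             w = w, C = C))
}

mscam_bwd <- function(dW, cache, params, gr) {
  dPre <- dW * cache$w * (1 - cache$w)
  dGa <- linear_bwd(dPre, cache$g2, params, gr)
  dG1 <- relu_bwd(dGa, cache$ga)
  dGin <- linear_bwd(dG1, cache$g1, params, gr)
  dJ_global <- matrix(rowSums(dGin) / cache$C, nrow(dGin), cache$C)
  dLa <- linear_bwd(dPre, cache$l2, params, gr)
  dL1 <- relu_bwd(dLa, cache$la)
  dJ_local <- linear_bwd(dL1, cache$l1, params, gr)
  dJ_global + dJ_local
}

aff_fuse_fwd <- function(X, Y, params) {
  if (!identical(dim(X), dim(Y))) abort("AFF inputs must have equal shape")
  J <- X + Y
  ms <- mscam_fwd(J, params)
  w <- ms$out
  Z <- w * X + (1 - w) * Y
  list(out = Z, w = w, cache = list(X = X, Y = Y, w = w, ms = ms$cache))
}

aff_fuse_bwd <- function(dZ, cache, params, gr) {
  w <- cache$w
  dX <- dZ * w
  dY <- dZ * (1 - w)
  dW <- dZ * (cache$X - cache$Y)
  dJ <- mscam_bwd(dW, cache$ms, params, gr)
  list(dX = dX + dJ, dY = dY + dJ)
}

#' Attentional feature fusion
#'
#' `Z = w * X + (1 - w) * Y` where `w = M(X + Y)` is the output of the
#' multi-scale channel attention block: the sum of a bottleneck transform
#' of the channel-mean-pooled signal (global context) and the same-shaped
#' bottleneck of the unpooled signal (local context), passed through a
#' sigmoid so `w` lies in `[0, 1]` elementwise.
#'
#' @param X,Y Feature matrices (`batch x out_dim`), pattern stream first.
#' @param model A `dicer_model` with `fusion = "aff"`.
#' @return A list with `Z` (fused features) and `w` (attention weights for
#'   the pattern stream `X`).
#' @export
aff_fuse <- function(X, Y, model) {
  if (model$config$fusion != "aff") abort("model was built with concat fusion")
  f <- aff_fuse_fwd(X, Y, model$params)
  list(Z = f$out, w = f$w)
}

#' Concatenation fusion
#'
#' @inheritParams aff_fuse
#' @return The `batch x 2*out_dim` matrix `[X | Y]`.
#' @export
concat_fuse <- function(X, Y) {
  cbind(X, Y)
}

#' Multi-scale channel attention weights
#'
#' @param J Joint feature matrix (`batch x out_dim`), typically `X + Y`.
#' @param model A `dicer_model` with AFF fusion.
#' @return Matrix of weights in `(0, 1)`, same shape as `J`.
#' @export
mscam <- function(J, model) {
  if (model$config$fusion != "aff") abort("model was built with concat fusion")
  mscam_fwd(J, model$params)$out
}

# --- full model ----------------------------------------------------------

# Forward over a batch of encoded samples (indices into `enc`). Returns
# logits/probs plus caches for the backward pass.
model_forward_batch <- function(model, enc, idx, training = FALSE) {
  cfg <- model$config
  params <- model$params
  pat_lens <- lengths(enc$pat_seq[idx])
  if (any(pat_lens != cfg$s)) abort("pattern length differs from config s")
  full_lens <- lengths(enc$full_seq[idx])
  if (any(full_lens > cfg$max_seq_len)) {
    abort(sprintf("hairpin longer than max_seq_len = %d", cfg$max_seq_len))
  }
  # Patterns from the same hairpin share the full-sequence stream; encode
  # each distinct hairpin once per batch and expand (exact, not an
  # approximation — gradients are summed over duplicates on the way back).
  hp <- enc$premirna_id[idx] %||% as.character(idx)
  uniq <- !duplicated(hp)
  expand <- match(hp, hp[uniq])
  uidx <- idx[uniq]
  pat_stream <- batch_stream(enc$pat_seq[idx], enc$pat_struct[idx], params)
  seq_stream <- batch_stream(enc$full_seq[uidx], enc$full_struct[uidx], params)
  pat_enc <- encoder_unit_fwd(pat_stream, params, "pat", cfg, training)
  seq_enc <- encoder_unit_fwd(seq_stream, params, "seq", cfg, training)
  seq_out <- seq_enc$out[expand, , drop = FALSE]
  if (cfg$fusion == "aff") {
    fuse <- aff_fuse_fwd(pat_enc$out, seq_out, params)
    fused <- fuse$out
    w <- fuse$w
    fuse_cache <- fuse$cache
  } else {
    fused <- cbind(pat_enc$out, seq_out)
    w <- NULL
    fuse_cache <- NULL
  }
  fc1 <- linear_fwd(fused, params, "head.fc1")
  a1 <- leaky_relu_fwd(fc1$out, cfg$leaky_slope)
  fc2 <- linear_fwd(a1$out, params, "head.fc2")
  logits <- fc2$out
  list(
    logits = logits, probs = softmax_rows(logits), w = w,
    cache = list(pat_stream = pat_stream, seq_stream = seq_stream,
                 pat_enc = pat_enc$cache, seq_enc = seq_enc$cache,
                 expand = expand,
                 fuse = fuse_cache, fc1 = fc1$cache, a1 = a1$cache,
                 fc2 = fc2$cache)
  )
}

model_backward_batch <- function(model, fwd, dlogits) {
  cfg <- model$config
  params <- model$params
  gr <- new.env(parent = emptyenv())
  cache <- fwd$cache
  dA1 <- linear_bwd(dlogits, cache$fc2, params, gr)
  dFc1 <- leaky_relu_bwd(dA1, cache$a1)
  dFused <- linear_bwd(dFc1, cache$fc1, params, gr)
  if (cfg$fusion == "aff") {
    d <- aff_fuse_bwd(dFused, cache$fuse, params, gr)
    dPat <- d$dX
    dSeq <- d$dY
  } else {
    dPat <- dFused[, seq_len(cfg$out_dim), drop = FALSE]
    dSeq <- dFused[, cfg$out_dim + seq_len(cfg$out_dim), drop = FALSE]
  }
  # collapse duplicate-hairpin gradients back onto the unique seq streams
  dSeqU <- rowsum(dSeq, cache$expand, reorder = TRUE)
  dPatStream <- encoder_unit_bwd(dPat, cache$pat_enc, params, gr, cfg)
  dSeqStream <- encoder_unit_bwd(dSeqU, cache$seq_enc, params, gr, cfg)
  stream_embedding_bwd(dPatStream, cache$pat_stream, params, gr)
  stream_embedding_bwd(dSeqStream, cache$seq_stream, params, gr)
  as.list(gr)
}

# embedding scatter-add (shared by both streams)
stream_embedding_bwd <- function(dX, stream, params, gr) {
  d_emb <- ncol(dX) / 2L
  dvalid <- dX[stream$valid_rows, , drop = FALSE]
  for (spec in list(list("emb.seq", seq_len(d_emb), stream$seq_ids),
                    list("emb.struct", d_emb + seq_len(d_emb), stream$struct_ids))) {
    nm <- spec[[1]]
    g <- rowsum(dvalid[, spec[[2]], drop = FALSE], spec[[3]])
    ids <- as.integer(rownames(g))
    cur <- gr[[nm]]
    if (is.null(cur)) cur <- matrix(0, nrow(params[[nm]]), d_emb)
    cur[ids, ] <- cur[ids, , drop = FALSE] + g
    gr[[nm]] <- cur
  }
  invisible(NULL)
}

#' Predict class probabilities for a pattern dataset
#'
#' Runs the forward pass in evaluation mode (no dropout) in mini-batches.
#'
#' @param object A trained `dicer_model`.
#' @param dataset A `dicer_dataset` (or any tibble with the dataset
#'   columns).
#' @param batch_size Mini-batch size for the forward pass.
#' @param ... Unused.
#' @return A tibble with `pattern_id`, `label`, `pred`, and a matrix column
#'   `prob` of class probabilities (and `aff_w`, the mean pattern-stream
#'   attention weight, for AFF models).
#' @export
predict.dicer_model <- function(object, dataset, batch_size = 128L, ...) {
  enc <- encode_dataset(dataset, object)
  n <- nrow(dataset)
  batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  probs <- matrix(NA_real_, n, object$config$n_classes)
  wmean <- rep(NA_real_, n)
  for (idx in batches) {
    fwd <- model_forward_batch(object, enc, idx, training = FALSE)
    probs[idx, ] <- fwd$probs
    if (!is.null(fwd$w)) wmean[idx] <- rowMeans(fwd$w)
  }
  out <- tibble::tibble(
    pattern_id = dataset$pattern_id,
    label = as.integer(dataset$label),
    pred = max.col(probs, ties.method = "first") - 1L,
    prob = probs
  )
  if (object$config$fusion == "aff") out$aff_w <- wmean
  out
}

#' Rank classes by predicted probability
#'
#' Ties are broken toward the lower class index.
#'
#' @param probs A probability vector, or a matrix with one row per sample.
#' @param k How many top classes to return.
#' @return An integer vector of 0-based classes (or a matrix, one row per
#'   sample).
#' @export
predict_topk <- function(probs, k = 3L) {
  rank_row <- function(p) order(-p, seq_along(p))[seq_len(k)] - 1L
  if (is.matrix(probs)) {
    out <- apply(probs, 1, rank_row)
    # apply() drops to a vector when k = 1; keep samples in rows
    if (k == 1L) matrix(out, ncol = 1L) else t(out)
  } else {
    rank_row(probs)
  }
}

#' AFF attention-weight diagnostics
#'
#' Reports the distribution of the pattern-stream fusion weight `w` over a
#' dataset: per-sample mean weights plus summary statistics. Purely
#' diagnostic — no assertion is made on the values.
#'
#' @param model A trained `dicer_model` with AFF fusion.
#' @param dataset A `dicer_dataset`.
#' @param batch_size Forward-pass batch size.
#' @return A list with `per_sample` (tibble of `pattern_id`, `mean_w`) and
#'   `summary` (mean/min/max).
#' @export
aff_weight_diagnostics <- function(model, dataset, batch_size = 128L) {
  if (model$config$fusion != "aff") {
    abort("attention diagnostics require a model with AFF fusion")
  }
  preds <- predict(model, dataset, batch_size = batch_size)
  list(
    per_sample = tibble::tibble(pattern_id = preds$pattern_id,
                                mean_w = preds$aff_w),
    summary = c(mean = mean(preds$aff_w), min = min(preds$aff_w),
                max = max(preds$aff_w))
  )
}

# --- checkpoints ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint holds the weights, the full configuration, both
#' vocabularies and the init seed, so inference is reproducible.
#'
#' @param model A `dicer_model`.
#' @param path Checkpoint file path (`.rds`).
#' @return `save_checkpoint()` returns the path invisibly;
#'   `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dicer_model")) abort("not a dicer_model checkpoint")
  model
}
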