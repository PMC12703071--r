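# Minimal neural-network engine: the layers the cleavage-site model needs,
# written directly on BLAS matrix ops with hand-derived backward passes.
#
# Batch layout: a stream holds B samples of P positions each as a
# (B*P) x D matrix with sample-contiguous rows (sample b occupies rows
# (b-1)*P + 1 .. b*P). `mask` flags valid (non-pad) positions; the
# invariant maintained throughout the encoder is that pad rows are exactly
# zero after every sublayer, which makes all outputs independent of the
# pad length.
#
# Every *_fwd() returns list(out, cache); every *_bwd() consumes the
# upstream gradient and the cache, writes parameter gradients into the
# environment `gr` (keyed like the parameter list) and returns the
# gradient with respect to its input.

acc_grad <- function(gr, name, value) {
  if (is.null(gr[[name]])) gr[[name]] <- value else gr[[name]] <- gr[[name]] + value
  invisible(NULL)
}

add_row_vec <- function(X, v) {
  X + matrix(v, nrow(X), length(v), byrow = TRUE)
}

row_max <- function(S) {
  S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
}

linear_fwd <- function(X, params, prefix) {
  W <- params[[paste0(prefix, ".W")]]
  b <- params[[paste0(prefix, ".b")]]
  out <- add_row_vec(X %*% W, b)
  list(out = out, cache = list(X = X, prefix = prefix))
}

linear_bwd <- function(dY, cache, params, gr) {
  prefix <- cache$prefix
  acc_grad(gr, paste0(prefix, ".W"), crossprod(cache$X, dY))
  acc_grad(gr, paste0(prefix, ".b"), colSums(dY))
  dY %*% t(params[[paste0(prefix, ".W")]])
}

layernorm_fwd <- function(X, params, prefix, eps = 1e-5) {
  g <- params[[paste0(prefix, ".g")]]
  b <- params[[paste0(prefix, ".b")]]
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  out <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, prefix = prefix))
}

layernorm_bwd <- function(dY, cache, params, gr) {
  prefix <- cache$prefix
  g <- params[[paste0(prefix, ".g")]]
  xhat <- cache$xhat
  acc_grad(gr, paste0(prefix, ".g"), colSums(dY * xhat))
  acc_grad(gr, paste0(prefix, ".b"), colSums(dY))
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  (dxhat - m1 - xhat * m2) * cache$inv_sd
}

leaky_relu_fwd <- function(X, slope = 0.01) {
  neg <- X < 0
  out <- X
  out[neg] <- slope * X[neg]
  list(out = out, cache = list(neg = neg, slope = slope))
}

leaky_relu_bwd <- function(dY, cache) {
  dY[cache$neg] <- cache$slope * dY[cache$neg]
  dY
}

relu_fwd <- function(X) {
  neg <- X < 0
  out <- X
  out[neg] <- 0
  list(out = out, cache = neg)
}

relu_bwd <- function(dY, neg) {
  dY[neg] <- 0
  dY
}

dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) {
    return(list(out = X, cache = NULL))
  }
  keep <- (matrix(runif(length(X)), nrow(X)) >= p) / (1 - p)
  list(out = X * keep, cache = keep)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

zero_pad_rows <- function(X, mask) {
  if (!all(mask)) X[!mask, ] <- 0
  X
}

# Multi-head self-attention over a batched stream. Pad keys are excluded
# from every softmax; outputs at pad query positions are zeroed by the
# caller's masking step.
mha_fwd <- function(X, mask, B, P, params, prefix, n_heads) {
  D <- ncol(X)
  dk <- D / n_heads
  q <- linear_fwd(X, params, paste0(prefix, ".q"))
  k <- linear_fwd(X, params, paste0(prefix, ".k"))
  v <- linear_fwd(X, params, paste0(prefix, ".v"))
  Q <- q$out; K <- k$out; V <- v$out
  O <- matrix(0, nrow(X), D)
  A_list <- vector("list", B)
  scale <- 1 / sqrt(dk)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * P + 1L):(b * P)
    mk <- mask[rows]
    Ab <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- tcrossprod(Q[rows, cols, drop = FALSE], K[rows, cols, drop = FALSE]) * scale
      S[, !mk] <- -1e30
      E <- exp(S - row_max(S))
      A <- E / rowSums(E)
      Ab[[h]] <- A
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
    }
    A_list[[b]] <- Ab
  }
  o <- linear_fwd(O, params, paste0(prefix, ".o"))
  list(out = o$out, cache = list(
    q = q$cache, k = k$cache, v = v$cache, o = o$cache,
    Q = Q, K = K, V = V, A = A_list, B = B, P = P,
    n_heads = n_heads, scale = scale, prefix = prefix
  ))
}

mha_bwd <- function(dY, cache, params, gr) {
  B <- cache$B; P <- cache$P; H <- cache$n_heads
  D <- ncol(cache$Q)
  dk <- D / H
  dO <- linear_bwd(dY, cache$o, params, gr)
  dQ <- matrix(0, nrow(dO), D)
  dK <- matrix(0, nrow(dO), D)
  dV <- matrix(0, nrow(dO), D)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * P + 1L):(b * P)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cache$A[[b]][[h]]
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOb, Vb)
      dV[rows, cols] <- dV[rows, cols] + crossprod(A, dOb)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] * cache$scale
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) * cache$scale
    }
  }
  dX <- linear_bwd(dQ, cache$q, params, gr) +
    linear_bwd(dK, cache$k, params, gr) +
    linear_bwd(dV, cache$v, params, gr)
  dX
}

# Shift a sample-contiguous stream by `o` positions (source p + o), filling
# with zero rows across sample boundaries.
shift_stream <- function(X, B, P, o) {
  if (o == 0L) return(X)
  Xz <- rbind(X, 0)
  p <- seq_len(P)
  src <- p + o
  idx <- ifelse(src >= 1L & src <= P, src, NA_integer_)
  full <- rep((seq_len(B) - 1L) * P, each = P) + rep(idx, B)
  full[is.na(full)] <- nrow(Xz)
  Xz[full, , drop = FALSE]
}

# Same-padding 1D convolution along positions, channels D -> D, odd kernel.
# Weights are stored as a (kernel*D) x D matrix, one D-block per offset.
conv1d_fwd <- function(X, B, P, params, prefix, kernel) {
  offsets <- seq_len(kernel) - (kernel + 1L) %/% 2L
  Xstack <- do.call(cbind, lapply(offsets, function(o) shift_stream(X, B, P, o)))
  W <- params[[paste0(prefix, ".W")]]
  b <- params[[paste0(prefix, ".b")]]
  out <- add_row_vec(Xstack %*% W, b)
  list(out = out, cache = list(Xstack = Xstack, B = B, P = P,
                               offsets = offsets, prefix = prefix, D = ncol(X)))
}

conv1d_bwd <- function(dY, cache, params, gr) {
  prefix <- cache$prefix
  W <- params[[paste0(prefix, ".W")]]
  acc_grad(gr, paste0(prefix, ".W"), crossprod(cache$Xstack, dY))
  acc_grad(gr, paste0(prefix, ".b"), colSums(dY))
  dXstack <- dY %*% t(W)
  D <- cache$D
  dX <- 0
  for (i in seq_along(cache$offsets)) {
    o <- cache$offsets[[i]]
    block <- dXstack[, ((i - 1L) * D + 1L):(i * D), drop = FALSE]
    dX <- dX + shift_stream(block, cache$B, cache$P, -o)
  }
  dX
}

# Mean over valid positions of each sample.
masked_mean_fwd <- function(X, mask, B, P) {
  group <- rep(seq_len(B), each = P)
  lens <- as.vector(rowsum(as.numeric(mask), group))
  pooled <- rowsum(X, group) / lens
  list(out = pooled, cache = list(mask = mask, B = B, P = P, lens = lens))
}

masked_mean_bwd <- function(dY, cache) {
  B <- cache$B; P <- cache$P
  per_row <- dY / cache$lens
  dX <- per_row[rep(seq_len(B), each = P), , drop = FALSE]
  dX[!cache$mask, ] <- 0
  dX
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(X) {
  E <- exp(X - apply(X, 1, max))
  E / rowSums(E)
}

# Softmax + cross-entropy over a batch; labels are 0-based classes.
softmax_ce <- function(logits, labels) {
  probs <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / n
  list(loss = loss, probs = probs, dlogits = dlogits)
}

# --- parameter initialisation -------------------------------------------

# fan-in scaled uniform init (PyTorch nn.Linear default)
init_linear <- function(params, prefix, n_in, n_out) {
  bound <- 1 / sqrt(n_in)
  params[[paste0(prefix, ".W")]] <- matrix(runif(n_in * n_out, -bound, bound), n_in, n_out)
  params[[paste0(prefix, ".b")]] <- runif(n_out, -bound, bound)
  params
}

init_layernorm <- function(params, prefix, dim) {
  params[[paste0(prefix, ".g")]] <- rep(1, dim)
  params[[paste0(prefix, ".b")]] <- rep(0, dim)
  params
}

# --- AdamW ---------------------------------------------------------------

adamw_state <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adamw_step <- function(params, grads, state, lr, weight_decay = 1e-5,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}
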