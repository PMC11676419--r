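# Attention machinery used after each decoder upsampling stage: patch
# tokenization, sinusoidal positional encoding, multi-head self-attention,
# position-wise feed-forward network, and the full residual Add&Norm block.
# Tokens are plain matrices (length x dim), one row per token.

#' Tokenize a feature map into a patch sequence
#'
#' Each non-overlapping `patch x patch` spatial patch becomes one token whose
#' embedding stacks the patch's pixels across all channels, so with
#' `patch = 1` there is one token per pixel of dimension `channels`. The
#' mapping is lossless and inverted exactly by [detokenize()].
#'
#' @param x Rank-3 feature map (height x width x channels).
#' @param patch Patch edge length in pixels; must divide both spatial dims.
#' @return A matrix of dim `(h/patch * w/patch) x (channels * patch^2)` with
#'   attribute `origin = c(height, width, patch)`.
#' @export
tokenize <- function(x, patch = 1L) {
  check_feature_map(x)
  d <- dim(x); patch <- as.integer(patch)
  if (d[1] %% patch != 0L || d[2] %% patch != 0L)
    stop(sprintf("tokenize: spatial dims (%d x %d) not divisible by patch %d",
                 d[1], d[2], patch))
  nh <- d[1] %/% patch; nw <- d[2] %/% patch
  if (patch == 1L) {
    tk <- matrix(x, nh * nw, d[3])
  } else {
    # dims: (patch_row, block_row, patch_col, block_col, channel)
    xp <- array(x, dim = c(patch, nh, patch, nw, d[3]))
    xp <- aperm(xp, c(2, 4, 1, 3, 5))   # (block_row, block_col, pr, pc, ch)
    tk <- matrix(xp, nh * nw, patch * patch * d[3])
  }
  attr(tk, "origin") <- c(d[1], d[2], patch)
  tk
}

#' Invert [tokenize()]
#'
#' @param tokens Token matrix carrying the `origin` attribute set by
#'   [tokenize()] (or passed via `origin`).
#' @param origin Optional `c(height, width, patch)` override.
#' @return The original rank-3 feature map.
#' @export
detokenize <- function(tokens, origin = attr(tokens, "origin")) {
  if (is.null(origin)) stop("detokenize: no origin information")
  h <- origin[1]; w <- origin[2]; patch <- origin[3]
  nh <- h %/% patch; nw <- w %/% patch
  ch <- ncol(tokens) %/% (patch * patch)
  if (patch == 1L) return(array(tokens, dim = c(h, w, ch)))
  xp <- array(tokens, dim = c(nh, nw, patch, patch, ch))
  xp <- aperm(xp, c(3, 1, 4, 2, 5))
  array(xp, dim = c(h, w, ch))
}

#' Sinusoidal positional encoding table
#'
#' Deterministic, parameter-free encoding: position `p` (0-based) gets
#' `sin(p / 10000^(2i/dim))` in even columns and the matching cosine in odd
#' columns. All entries lie in `[-1, 1]` and rows are pairwise distinct for
#' any practical sequence length.
#'
#' @param length Number of positions.
#' @param dim Embedding dimension; must be even.
#' @return A `length x dim` matrix of offsets to add to token embeddings.
#' @export
positional_encoding <- function(length, dim) {
  if (dim %% 2L != 0L) stop("positional_encoding: dim must be even")
  pos <- seq_len(length) - 1
  i <- seq_len(dim %/% 2L) - 1
  freq <- 1 / 10000^(2 * i / dim)
  ang <- outer(pos, freq)
  pe <- matrix(0, length, dim)
  pe[, seq(1L, dim, by = 2L)] <- sin(ang)
  pe[, seq(2L, dim, by = 2L)] <- cos(ang)
  pe
}

# internal: encoding truncated to a possibly-odd dimension
positional_encoding_any <- function(length, dim) {
  pe <- positional_encoding(length, dim + dim %% 2L)
  pe[, seq_len(dim), drop = FALSE]
}

#' Multi-head self-attention weights
#'
#' Draws query/key/value and output projection matrices (He-normal, current
#' RNG state) for [mhsa()]. The per-head width is `dim / heads`.
#'
#' @param dim Token embedding dimension.
#' @param heads Number of attention heads; must divide `dim`.
#' @return An object of class `attention_weights`.
#' @export
attention_weights <- function(dim, heads = 4L) {
  if (heads < 1L || dim %% heads != 0L)
    stop("attention_weights: heads must be >= 1 and divide dim")
  w <- list(Wq = he_normal_init(dim, c(dim, dim)),
            Wk = he_normal_init(dim, c(dim, dim)),
            Wv = he_normal_init(dim, c(dim, dim)),
            Wo = he_normal_init(dim, c(dim, dim)),
            bq = numeric(dim), bk = numeric(dim),
            bv = numeric(dim), bo = numeric(dim),
            heads = as.integer(heads), dim = as.integer(dim))
  class(w) <- "attention_weights"
  w
}

softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

#' Multi-head self-attention
#'
#' Per head `i`: `H_i = softmax(Q_i K_i^T / sqrt(d_h)) V_i` with
#' `Q_i = X W_qi` (etc.); head outputs are concatenated and passed through the
#' output projection. Attention rows are probability vectors.
#'
#' @param X Token matrix (length x dim).
#' @param W An [attention_weights()] object with matching `dim`.
#' @return Token matrix of the same shape.
#' @export
mhsa <- function(X, W) {
  stopifnot(inherits(W, "attention_weights"))
  if (ncol(X) != W$dim)
    stop(sprintf("mhsa: token dim %d does not match weights dim %d", ncol(X), W$dim))
  n <- W$heads; dh <- W$dim %/% n
  Q <- sweep(X %*% W$Wq, 2L, W$bq, "+")
  K <- sweep(X %*% W$Wk, 2L, W$bk, "+")
  V <- sweep(X %*% W$Wv, 2L, W$bv, "+")
  H <- matrix(0, nrow(X), W$dim)
  for (i in seq_len(n)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    A <- softmax_rows(tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh))
    H[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  sweep(H %*% W$Wo, 2L, W$bo, "+")
}

#' Feed-forward network weights
#'
#' @param dim Token embedding dimension.
#' @param d_ff Hidden width of the position-wise network.
#' @return An object of class `ffn_weights`.
#' @export
ffn_weights <- function(dim, d_ff) {
  w <- list(W1 = he_normal_init(dim, c(dim, d_ff)), b1 = numeric(d_ff),
            W2 = he_normal_init(d_ff, c(d_ff, dim)), b2 = numeric(dim))
  class(w) <- "ffn_weights"
  w
}

#' Position-wise feed-forward network
#'
#' `FFN(X) = max(0, X W1 + b1) W2 + b2`, applied identically to every token.
#'
#' @param X Token matrix (length x dim).
#' @param W An [ffn_weights()] object.
#' @return Token matrix of the same shape.
#' @export
ffn <- function(X, W) {
  stopifnot(inherits(W, "ffn_weights"))
  if (ncol(X) != nrow(W$W1)) stop("ffn: token dim does not match W1")
  h <- sweep(X %*% W$W1, 2L, W$b1, "+")
  h[h < 0] <- 0
  sweep(h %*% W$W2, 2L, W$b2, "+")
}

# ---- differentiable transformer layers (used inside models) ----------------

layer_mhsa <- function(dim, heads) {
  if (heads < 1L || dim %% heads != 0L) stop("layer_mhsa: heads must divide dim")
  l <- new_layer("mhsa")
  l$dim <- as.integer(dim); l$heads <- as.integer(heads)
  l$params$Wq <- he_normal_init(dim, c(dim, dim))
  l$params$Wk <- he_normal_init(dim, c(dim, dim))
  l$params$Wv <- he_normal_init(dim, c(dim, dim))
  l$params$Wo <- he_normal_init(dim, c(dim, dim))
  l$params$bq <- numeric(dim); l$params$bk <- numeric(dim)
  l$params$bv <- numeric(dim); l$params$bo <- numeric(dim)
  l$fwd <- function(x, training = FALSE) {
    n <- l$heads; dh <- l$dim %/% n
    Q <- sweep(x %*% l$params$Wq, 2L, l$params$bq, "+")
    K <- sweep(x %*% l$params$Wk, 2L, l$params$bk, "+")
    V <- sweep(x %*% l$params$Wv, 2L, l$params$bv, "+")
    H <- matrix(0, nrow(x), l$dim)
    As <- if (training) vector("list", n) else NULL
    for (i in seq_len(n)) {
      cols <- ((i - 1L) * dh + 1L):(i * dh)
      A <- softmax_rows(tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh))
      if (training) As[[i]] <- A
      H[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    if (training) l$cache <- list(x = x, Q = Q, K = K, V = V, A = As, H = H)
    sweep(H %*% l$params$Wo, 2L, l$params$bo, "+")
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    n <- l$heads; dh <- l$dim %/% n
    l$grads$Wo <- l$grads$Wo + crossprod(cc$H, dy)
    l$grads$bo <- l$grads$bo + colSums(dy)
    dH <- tcrossprod(dy, l$params$Wo)
    dQ <- matrix(0, nrow(dy), l$dim)
    dK <- dQ; dV <- dQ
    for (i in seq_len(n)) {
      cols <- ((i - 1L) * dh + 1L):(i * dh)
      A <- cc$A[[i]]
      dHi <- dH[, cols, drop = FALSE]
      dA <- tcrossprod(dHi, cc$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dHi)
      dS <- A * (dA - rowSums(dA * A))          # softmax backward, row-wise
      dS <- dS / sqrt(dh)
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE]
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE])
    }
    l$grads$Wq <- l$grads$Wq + crossprod(cc$x, dQ)
    l$grads$Wk <- l$grads$Wk + crossprod(cc$x, dK)
    l$grads$Wv <- l$grads$Wv + crossprod(cc$x, dV)
    l$grads$bq <- l$grads$bq + colSums(dQ)
    l$grads$bk <- l$grads$bk + colSums(dK)
    l$grads$bv <- l$grads$bv + colSums(dV)
    dx <- tcrossprod(dQ, l$params$Wq) + tcrossprod(dK, l$params$Wk) +
      tcrossprod(dV, l$params$Wv)
    l$cache <- NULL
    dx
  }
  zero_grads_layer(l)
  l
}

layer_ffn <- function(dim, d_ff) {
  l <- new_layer("ffn")
  l$lin1 <- layer_linear(dim, d_ff)
  l$relu <- layer_relu()
  l$lin2 <- layer_linear(d_ff, dim)
  # expose child params through a flat registry walk (see collect_layers)
  l$children <- list(l$lin1, l$relu, l$lin2)
  l$fwd <- function(x, training = FALSE) {
    h <- l$lin1$fwd(x, training)
    h <- l$relu$fwd(h, training)
    l$lin2$fwd(h, training)
  }
  l$bwd <- function(dy) l$lin1$bwd(l$relu$bwd(l$lin2$bwd(dy)))
  l
}

# ---- full transformer block -------------------------------------------------

# tokenize -> linear patch embedding (to d_model = channels) -> + positional
# encoding -> MHSA -> Add & Norm -> FFN -> Add & Norm -> linear unembedding ->
# detokenize. Post-norm by default (Add then Norm); "pre" places the
# normalization before each sub-layer instead.
new_transformer_block <- function(channels, patch, heads, d_ff,
                                  norm_placement = c("post", "pre")) {
  norm_placement <- match.arg(norm_placement)
  token_dim <- channels * patch * patch
  d_model <- channels
  eff_heads <- heads
  while (d_model %% eff_heads != 0L) eff_heads <- eff_heads - 1L
  b <- new_block("transformer", list())
  b$patch <- as.integer(patch)
  b$channels <- channels
  b$norm_placement <- norm_placement
  b$embed <- layer_linear(token_dim, d_model)
  b$attn <- layer_mhsa(d_model, eff_heads)
  b$norm1 <- layer_layernorm(d_model)
  b$ffn <- layer_ffn(d_model, d_ff)
  b$norm2 <- layer_layernorm(d_model)
  b$unembed <- layer_linear(d_model, token_dim)
  b$layers <- list(b$embed, b$attn, b$norm1, b$ffn$lin1, b$ffn$lin2,
                   b$norm2, b$unembed)
  b$out_ch <- channels
  b$forward <- function(x, training) {
    tk <- tokenize(x, b$patch)
    b$origin <- attr(tk, "origin")
    e <- b$embed$fwd(tk, training)
    e <- e + positional_encoding_any(nrow(e), ncol(e))
    if (b$norm_placement == "post") {
      a <- b$attn$fwd(e, training)
      x1 <- b$norm1$fwd(e + a, training)
      f <- b$ffn$fwd(x1, training)
      x2 <- b$norm2$fwd(x1 + f, training)
    } else {
      a <- b$attn$fwd(b$norm1$fwd(e, training), training)
      x1 <- e + a
      f <- b$ffn$fwd(b$norm2$fwd(x1, training), training)
      x2 <- x1 + f
    }
    u <- b$unembed$fwd(x2, training)
    detokenize(u, b$origin)
  }
  b$backward <- function(dy) {
    du <- tokenize(dy, b$patch)
    dx2 <- b$unembed$bwd(du)
    if (b$norm_placement == "post") {
      ds <- b$norm2$bwd(dx2)
      dx1 <- ds + b$ffn$bwd(ds)
      ds1 <- b$norm1$bwd(dx1)
      de <- ds1 + b$attn$bwd(ds1)
    } else {
      dx1 <- dx2 + b$norm2$bwd(b$ffn$bwd(dx2))
      de <- dx1 + b$norm1$bwd(b$attn$bwd(dx1))
    }
    dtk <- b$embed$bwd(de)
    detokenize(dtk, b$origin)
  }
  b
}

#' Transformer block applied to a feature map
#'
#' Tokenizes the map into patches, linearly embeds each patch, adds sinusoidal
#' positional encodings, then applies multi-head self-attention and a
#' position-wise feed-forward network, each wrapped in a residual Add&Norm,
#' and finally unembeds back to the input shape. Weights are drawn from the
#' current RNG state.
#'
#' @param x Feature map whose spatial dims are divisible by `patch`.
#' @param patch Patch edge length.
#' @param heads Requested head count (reduced to the nearest divisor of the
#'   channel width when necessary).
#' @param d_ff Hidden width of the feed-forward sub-layer.
#' @param norm_placement `"post"` (Add then Norm, the default) or `"pre"`.
#' @return Feature map of the same shape as `x`.
#' @export
transformer_block <- function(x, patch = 1L, heads = 4L, d_ff = 4L * dim(x)[3],
                              norm_placement = "post") {
  check_feature_map(x)
  b <- new_transformer_block(dim(x)[3], patch, heads, d_ff, norm_placement)
  block_forward(b, x)
}
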