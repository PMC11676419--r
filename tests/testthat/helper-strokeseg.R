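# Shared fixtures and independent oracles used across the suite.

# small feature map with reproducible content
rand_map <- function(h, w, c, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(h * w * c), dim = c(h, w, c))
}

tiny_model_config <- function(variant = "transformer_dil_denseunet",
                              dropout = 0) {
  model_config(variant = variant, stem_width = 8L, growth = 4L,
               dense_layers = 2L, dilated_channels = 8L, heads = 2L,
               d_ff = 16L, dropout = dropout)
}

# brute-force multi-head self-attention: explicit per-head loops and row-wise
# softmax, independent of the package's vectorized path
mhsa_oracle <- function(X, W) {
  n <- W$heads; dh <- W$dim / n
  Q <- X %*% W$Wq + matrix(W$bq, nrow(X), W$dim, byrow = TRUE)
  K <- X %*% W$Wk + matrix(W$bk, nrow(X), W$dim, byrow = TRUE)
  V <- X %*% W$Wv + matrix(W$bv, nrow(X), W$dim, byrow = TRUE)
  H <- matrix(0, nrow(X), W$dim)
  for (i in seq_len(n)) {
    cols <- ((i - 1) * dh + 1):(i * dh)
    for (r in seq_len(nrow(X))) {
      scores <- numeric(nrow(X))
      for (s in seq_len(nrow(X)))
        scores[s] <- sum(Q[r, cols] * K[s, cols]) / sqrt(dh)
      a <- exp(scores - max(scores))
      a <- a / sum(a)
      H[r, cols] <- as.numeric(t(a) %*% V[, cols, drop = FALSE])
    }
  }
  H %*% W$Wo + matrix(W$bo, nrow(X), W$dim, byrow = TRUE)
}

# row-softmax attention matrix of one head, for the probability-row property
attention_matrix <- function(X, W, head) {
  dh <- W$dim / W$heads
  cols <- ((head - 1) * dh + 1):(head * dh)
  Q <- (X %*% W$Wq + matrix(W$bq, nrow(X), W$dim, byrow = TRUE))[, cols, drop = FALSE]
  K <- (X %*% W$Wk + matrix(W$bk, nrow(X), W$dim, byrow = TRUE))[, cols, drop = FALSE]
  S <- Q %*% t(K) / sqrt(dh)
  t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
}

# elementwise/token-loop FFN oracle
ffn_oracle <- function(X, W) {
  out <- matrix(0, nrow(X), ncol(X))
  for (r in seq_len(nrow(X))) {
    h <- as.numeric(X[r, ] %*% W$W1) + W$b1
    h[h < 0] <- 0
    out[r, ] <- as.numeric(h %*% W$W2) + W$b2
  }
  out
}

# per-pixel loop confusion oracle
confusion_oracle <- function(y, pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y)) {
    if (y[i] == 1 && pred[i] == 1) tp <- tp + 1L
    if (y[i] == 0 && pred[i] == 0) tn <- tn + 1L
    if (y[i] == 0 && pred[i] == 1) fp <- fp + 1L
    if (y[i] == 1 && pred[i] == 0) fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# standard deviation of a normal truncated at +/- 2 sigma
truncnorm_sd <- function(sigma) {
  a <- 2
  sigma * sqrt(1 - 2 * a * dnorm(a) / (pnorm(a) - pnorm(-a)))
}

# one small preprocessed phantom slice pair with a sizeable lesion
phantom_pair_64 <- function(seed = 7) {
  sp <- phantom_spec(n_subjects = 1, n_slices = 9, slice_size = 64,
                     blank_margin = c(2, 2), lesion_radius = c(5, 10),
                     seed = seed)
  ph <- make_phantom(sp, 1)
  prs <- preprocess_volume(ph$volume, ph$mask, target = 64)
  prs[[which.max(vapply(prs, function(p) sum(p$mask), 0))]]
}

phantom_pairs_64 <- function(n, seed = 21) {
  sp <- phantom_spec(n_subjects = 1, n_slices = n + 4, slice_size = 64,
                     blank_margin = c(2, 2), lesion_count = c(2, 3),
                     lesion_radius = c(5, 12), seed = seed)
  ph <- make_phantom(sp, 1)
  prs <- preprocess_volume(ph$volume, ph$mask, target = 64)
  prs[seq_len(min(n, length(prs)))]
}
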