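# Attention machinery: tokenization round trips, positional encoding closed
# forms, MHSA and FFN against brute-force oracles, block-level properties.

test_that("tokenization counts patches and inverts losslessly", {
  x <- rand_map(4, 4, 8, seed = 1)
  t1 <- tokenize(x, 1)
  expect_identical(dim(t1), c(16L, 8L))
  t2 <- tokenize(x, 2)
  expect_identical(dim(t2), c(4L, 32L))
  expect_equal(detokenize(t1), x)
  expect_equal(detokenize(t2), x)
  expect_error(tokenize(x, 3), "divisible")
})

test_that("positional encoding matches its closed form and separates positions", {
  pe <- positional_encoding(5, 6)
  expect_equal(pe[1, ], rep(c(0, 1), 3))      # sin 0 / cos 0 alternating
  expect_true(all(pe >= -1 & pe <= 1))
  big <- positional_encoding(1000, 32)
  expect_identical(nrow(unique(round(big, 12))), 1000L)
  expect_error(positional_encoding(4, 5), "even")
})

test_that("multi-head self-attention matches the brute-force oracle", {
  set.seed(2)
  for (len in c(1, 2, 5, 8)) {
    for (hd in c(1, 2, 4)) {
      d <- 8
      W <- attention_weights(d, hd)
      X <- matrix(rnorm(len * d), len, d)
      expect_equal(mhsa(X, W), mhsa_oracle(X, W), tolerance = 1e-10)
      # every attention row is a probability vector
      for (h in seq_len(hd)) {
        A <- attention_matrix(X, W, h)
        expect_equal(rowSums(A), rep(1, len), tolerance = 1e-6)
        expect_true(all(A >= 0))
      }
    }
  }
})

test_that("attention degenerates and symmetrizes as the math dictates", {
  set.seed(3)
  W <- attention_weights(4, 2)
  # single token: softmax of a 1x1 score is 1, so output = value path only
  x1 <- matrix(rnorm(4), 1, 4)
  v <- (x1 %*% W$Wv + W$bv) %*% W$Wo + W$bo
  expect_equal(mhsa(x1, W), v, tolerance = 1e-12)
  # duplicated tokens give duplicated outputs
  xd <- rbind(x1, x1, x1)
  yd <- mhsa(xd, W)
  expect_equal(yd[1, ], yd[2, ])
  expect_equal(yd[2, ], yd[3, ])
  # permutation equivariance without positions, broken once positions are added
  X <- matrix(rnorm(6 * 4), 6, 4)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(mhsa(X[perm, ], W), mhsa(X, W)[perm, ], tolerance = 1e-10)
  pe <- positional_encoding(6, 4)
  expect_false(isTRUE(all.equal(mhsa(X[perm, ] + pe, W),
                                mhsa(X + pe, W)[perm, ])))
})

test_that("feed-forward network matches the token-loop oracle and its closed cases", {
  set.seed(4)
  W <- ffn_weights(4, 6)
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(ffn(X, W), ffn_oracle(X, W), tolerance = 1e-12)
  # zero weights: constant output b2
  W0 <- W; W0$W1[] <- 0; W0$W2[] <- 0; W0$b2 <- c(1, 2, 3, 4)
  expect_equal(ffn(X, W0), matrix(c(1, 2, 3, 4), 5, 4, byrow = TRUE))
  # non-positive input through an identity first layer dies at the ReLU
  Wi <- ffn_weights(4, 4); Wi$W1 <- diag(4); Wi$b1 <- rep(0, 4)
  Xneg <- -abs(X)
  expect_equal(ffn(Xneg, Wi),
               matrix(Wi$b2, 5, 4, byrow = TRUE), tolerance = 1e-12)
  expect_error(ffn(matrix(0, 2, 3), W), "dim")
})

test_that("transformer block preserves shape and finiteness for stage configs", {
  for (cc in list(c(12, 1), c(12, 2), c(8, 4))) {
    set.seed(5)
    x <- rand_map(8, 8, cc[1], seed = cc[1] + cc[2])
    y <- transformer_block(x, patch = cc[2], heads = 4, d_ff = 16)
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
  # odd channel width is handled (head count falls back to a divisor)
  set.seed(6)
  y <- transformer_block(rand_map(8, 8, 7, seed = 9), patch = 2, heads = 4, d_ff = 8)
  expect_identical(dim(y), c(8L, 8L, 7L))
})

test_that("layer normalization standardizes each token", {
  set.seed(7)
  l <- strokeseg:::layer_layernorm(16)
  x <- matrix(rnorm(8 * 16, mean = 3, sd = 2), 8, 16)
  y <- l$fwd(x)
  expect_equal(rowMeans(y), rep(0, 8), tolerance = 1e-10)
  expect_equal(apply(y, 1, function(r) mean(r^2)), rep(1, 8), tolerance = 1e-3)
})
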