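# Convolutional building blocks: shape contracts, receptive field, dense
# channel algebra, transition halving, upsampling round trips, determinism.

test_that("stem lifts a single-channel slice without changing resolution", {
  set.seed(1)
  x <- rand_map(192, 192, 1)
  y <- stem(x, 32)
  expect_identical(dim(y), c(192L, 192L, 32L))
  expect_true(all(is.finite(y)))
  y2 <- stem(rand_map(64, 64, 1), 8)
  expect_identical(dim(y2), c(64L, 64L, 8L))
  expect_error(stem(rand_map(8, 8, 4), 8), "single-channel")
})

test_that("dilated stack preserves resolution and has the predicted receptive field", {
  cfg <- ddb_config(dilated_channels = 6, growth = 2, dense_layers = 2, dropout = 0)
  set.seed(2)
  y <- dilated_block(rand_map(48, 48, 3), cfg)
  expect_identical(dim(y), c(48L, 48L, 6L))

  # unit impulse through a 1-channel stack: support must span 1 + 2*(2+4+8).
  # Weights are made positive so the ReLUs cannot clip any response path.
  set.seed(3)
  b <- strokeseg:::new_dilated_block(1, ddb_config(1, growth = 1, dense_layers = 1,
                                                   dropout = 0))
  for (l in b$layers) if (l$type == "conv2d") l$params$W <- abs(l$params$W)
  imp <- array(0, dim = c(41, 41, 1)); imp[21, 21, 1] <- 1
  out <- block_forward(b, imp)
  base <- out[1, 1, 1]   # constant response away from the impulse
  nz <- which(abs(out[, , 1] - base) > 1e-12, arr.ind = TRUE)
  expect_equal(range(nz[, 1]), c(21 - 14, 21 + 14))
  expect_equal(range(nz[, 2]), c(21 - 14, 21 + 14))

  # all-zero input with zero biases stays exactly zero (BN in inference mode)
  set.seed(4)
  z <- dilated_block(array(0, dim = c(12, 12, 2)), cfg)
  expect_true(all(z == 0))
})

test_that("dense block adds L*g channels and keeps the input stack intact", {
  set.seed(5)
  cfg <- ddb_config(dilated_channels = 32, growth = 16, dense_layers = 4, dropout = 0)
  y <- dense_block(rand_map(10, 10, 32), cfg)
  expect_identical(dim(y)[3], 32L + 4L * 16L)   # 96

  # concatenation identity: leading channels are the input itself
  x <- rand_map(8, 8, 8, seed = 6)
  cfg1 <- ddb_config(dilated_channels = 8, growth = 4, dense_layers = 1, dropout = 0)
  y1 <- dense_block(x, cfg1)
  expect_identical(dim(y1)[3], 12L)
  expect_equal(y1[, , 1:8], x)

  expect_error(ddb_config(8, growth = 4, dense_layers = 0), "dense_layers")

  # channel algebra over randomized configurations
  set.seed(7)
  for (i in 1:5) {
    cin <- sample(2:12, 1); L <- sample(1:4, 1); g <- sample(1:8, 1)
    cfgr <- ddb_config(dilated_channels = 4, growth = g, dense_layers = L, dropout = 0)
    yr <- dense_block(rand_map(6, 6, cin, seed = 100 + i), cfgr)
    expect_identical(dim(yr), c(6L, 6L, as.integer(cin + L * g)))
  }
})

test_that("DDB equals the dense block applied to the dilated block output", {
  cfg <- ddb_config(dilated_channels = 5, growth = 3, dense_layers = 2, dropout = 0)
  set.seed(8)
  b <- strokeseg:::new_ddb(4, cfg)
  x <- rand_map(12, 12, 4, seed = 9)
  y <- block_forward(b, x)
  y2 <- block_forward(b$dense, block_forward(b$dilated, x))
  expect_equal(y, y2)
  expect_identical(dim(y), c(12L, 12L, 5L + 2L * 3L))
  expect_true(all(is.finite(y)))
})

test_that("transition layer compresses channels and halves even spatial dims", {
  set.seed(10)
  y <- transition_layer(rand_map(48, 48, 96), transition_config(0.5))
  expect_identical(dim(y), c(24L, 24L, 48L))
  set.seed(11)
  y1 <- transition_layer(rand_map(8, 8, 10), transition_config(1.0))
  expect_identical(dim(y1), c(4L, 4L, 10L))
  expect_error(transition_layer(rand_map(47, 47, 4)), "even")
  expect_error(transition_config(0), "compression")
  expect_error(transition_config(stride = 3), "stride")
})

test_that("upsampling doubles resolution, halves channels, and inverts transition shapes", {
  set.seed(12)
  y <- upsample(rand_map(24, 24, 8))
  expect_identical(dim(y), c(48L, 48L, 4L))

  # nearest-neighbour sub-step replicates each pixel into a 2x2 block
  l <- strokeseg:::layer_upsample_nn()
  chk <- array(c(1, 3, 2, 4), dim = c(2, 2, 1))
  up <- l$fwd(chk)
  expect_equal(up[, , 1],
               matrix(c(1, 1, 3, 3, 1, 1, 3, 3, 2, 2, 4, 4, 2, 2, 4, 4), 4, 4))

  # down-then-up restores spatial dims
  set.seed(13)
  x <- rand_map(16, 16, 6)
  d <- transition_layer(x, transition_config(0.5))
  u <- upsample(d)
  expect_identical(dim(u)[1:2], dim(x)[1:2])
})

test_that("blocks are deterministic under a fixed seed", {
  cfg <- ddb_config(dilated_channels = 4, growth = 2, dense_layers = 2, dropout = 0.2)
  x <- rand_map(10, 10, 2, seed = 14)
  set.seed(99); y1 <- ddb(x, cfg)
  set.seed(99); y2 <- ddb(x, cfg)
  expect_identical(y1, y2)
})
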