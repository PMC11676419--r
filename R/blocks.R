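# Convolutional building blocks: stem, dilated block, dense block, their DDB
# composition, transition layer and decoder upsampling. Blocks are containers
# of layers with explicit forward/backward composition; the functional
# entry points (stem(), dilated_block(), ...) build a freshly initialized
# block from the current RNG state and apply it, which is the contract the
# shape/receptive-field properties are stated against.

#' Configuration of a Dilated Dense Block
#'
#' A DDB is a stack of dilated 3x3 convolutions (dilation rates doubling:
#' 2, 4, 8 by default) followed by a densely connected block in which every
#' layer's `growth`-channel output is concatenated onto the running feature
#' stack.
#'
#' @param dilated_channels Channels produced by each dilated convolution.
#' @param dilation_rates Strictly increasing integer dilation rates, each >= 1.
#' @param dense_layers Number of layers `L` in the dense block (>= 1).
#' @param growth Channels `g` added to the stack by each dense layer (>= 1).
#' @param dropout Dropout probability applied after each dense-layer
#'   convolution, in `[0, 1)`.
#' @return An object of class `ddb_config`.
#' @export
ddb_config <- function(dilated_channels, dilation_rates = c(2L, 4L, 8L),
                       dense_layers = 4L, growth, dropout = 0.2) {
  if (any(dilation_rates < 1) || any(diff(dilation_rates) <= 0))
    stop("ddb_config: dilation_rates must be strictly increasing and >= 1")
  if (dense_layers < 1) stop("ddb_config: dense_layers must be >= 1")
  if (growth < 1) stop("ddb_config: growth must be >= 1")
  if (dilated_channels < 1) stop("ddb_config: dilated_channels must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("ddb_config: dropout must be in [0, 1)")
  structure(list(dilated_channels = as.integer(dilated_channels),
                 dilation_rates = as.integer(dilation_rates),
                 dense_layers = as.integer(dense_layers),
                 growth = as.integer(growth),
                 dropout = dropout),
            class = "ddb_config")
}

#' Configuration of a transition layer
#'
#' @param compression Fraction `theta` of channels kept by the 1x1
#'   convolution, in `(0, 1]`.
#' @param stride Spatial downsampling factor of the strided 3x3 convolution
#'   (fixed at 2).
#' @return An object of class `transition_config`.
#' @export
transition_config <- function(compression = 0.5, stride = 2L) {
  if (compression <= 0 || compression > 1)
    stop("transition_config: compression must be in (0, 1]")
  if (stride != 2L) stop("transition_config: stride is fixed at 2")
  structure(list(compression = compression, stride = 2L),
            class = "transition_config")
}

check_feature_map <- function(x) {
  if (length(dim(x)) != 3L)
    stop("feature map must be a rank-3 array (height x width x channels)")
  if (any(!is.finite(x))) stop("feature map contains non-finite values")
  invisible(x)
}

# ---- generic block container ------------------------------------------------

new_block <- function(type, layers) {
  b <- new.env(parent = emptyenv())
  b$type <- type
  b$layers <- layers      # ordered list of ss_layer (sequential blocks)
  class(b) <- "ss_block"
  b
}

seq_forward <- function(layers, x, training) {
  for (l in layers) x <- l$fwd(x, training)
  x
}

seq_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- l$bwd(dy)
  dy
}

#' Run a block forward
#'
#' @param block A block built by one of the `new_*` constructors.
#' @param x Feature map, rank-3 array (height x width x channels).
#' @param training Logical; `TRUE` enables batch statistics, dropout and
#'   gradient caching.
#' @return The block's output feature map.
#' @export
block_forward <- function(block, x, training = FALSE) {
  check_feature_map(x)
  block$forward(x, training)
}

#' Backpropagate through a block
#'
#' Must follow a `block_forward(..., training = TRUE)` call; accumulates
#' parameter gradients inside the block and returns the gradient with respect
#' to the block input.
#'
#' @param block A block.
#' @param dy Gradient of the loss with respect to the block output.
#' @return Gradient with respect to the block input.
#' @export
block_backward <- function(block, dy) block$backward(dy)

# ---- stem -------------------------------------------------------------------

new_stem <- function(in_ch, stem_width) {
  if (in_ch != 1L)
    stop("stem: input must be single-channel (one MRI modality at a time)")
  layers <- list(layer_conv2d(in_ch, stem_width, kernel = 3L),
                 layer_batchnorm(stem_width),
                 layer_relu())
  b <- new_block("stem", layers)
  b$out_ch <- stem_width
  b$forward <- function(x, training) seq_forward(b$layers, x, training)
  b$backward <- function(dy) seq_backward(b$layers, dy)
  b
}

# ---- dilated block ----------------------------------------------------------

new_dilated_block <- function(in_ch, cfg) {
  stopifnot(inherits(cfg, "ddb_config"))
  dc <- cfg$dilated_channels
  layers <- list()
  cin <- in_ch
  for (r in cfg$dilation_rates) {
    layers <- c(layers, list(layer_conv2d(cin, dc, kernel = 3L, dilation = r),
                             layer_batchnorm(dc),
                             layer_relu()))
    cin <- dc
  }
  b <- new_block("dilated_block", layers)
  b$out_ch <- dc
  b$forward <- function(x, training) seq_forward(b$layers, x, training)
  b$backward <- function(dy) seq_backward(b$layers, dy)
  b
}

# ---- dense block ------------------------------------------------------------

# Pre-activation ordering per layer (BN -> ReLU -> 3x3 conv -> dropout); the
# g-channel output of each layer is concatenated onto the running stack.
new_dense_block <- function(in_ch, cfg) {
  stopifnot(inherits(cfg, "ddb_config"))
  L <- cfg$dense_layers; g <- cfg$growth
  steps <- vector("list", L)
  cin <- in_ch
  for (j in seq_len(L)) {
    steps[[j]] <- list(bn = layer_batchnorm(cin),
                       relu = layer_relu(),
                       conv = layer_conv2d(cin, g, kernel = 3L),
                       drop = layer_dropout(cfg$dropout))
    cin <- cin + g
  }
  b <- new_block("dense_block", unlist(steps, recursive = FALSE))
  b$steps <- steps
  b$in_ch <- in_ch
  b$out_ch <- in_ch + L * g
  b$growth <- g
  b$forward <- function(x, training) {
    stack <- x
    for (st in b$steps) {
      h <- st$bn$fwd(stack, training)
      h <- st$relu$fwd(h, training)
      h <- st$conv$fwd(h, training)
      h <- st$drop$fwd(h, training)
      d <- dim(stack)
      stack <- array(c(stack, h), dim = c(d[1], d[2], d[3] + dim(h)[3]))
    }
    stack
  }
  b$backward <- function(dy) {
    g <- b$growth
    dstack <- dy
    for (st in rev(b$steps)) {
      cprev <- dim(dstack)[3] - g
      dh <- dstack[, , (cprev + 1):(cprev + g), drop = FALSE]
      dprev <- dstack[, , seq_len(cprev), drop = FALSE]
      dh <- st$drop$bwd(dh)
      dh <- st$conv$bwd(dh)
      dh <- st$relu$bwd(dh)
      dh <- st$bn$bwd(dh)
      dstack <- dprev + dh
    }
    dstack
  }
  b
}

# ---- DDB: dilated block feeding the dense block -----------------------------

new_ddb <- function(in_ch, cfg) {
  dil <- new_dilated_block(in_ch, cfg)
  den <- new_dense_block(cfg$dilated_channels, cfg)
  b <- new_block("ddb", c(dil$layers, den$layers))
  b$dilated <- dil
  b$dense <- den
  b$out_ch <- den$out_ch
  b$forward <- function(x, training) den$forward(dil$forward(x, training), training)
  b$backward <- function(dy) dil$backward(den$backward(dy))
  b
}

# ---- transition layer -------------------------------------------------------

new_transition <- function(in_ch, cfg) {
  stopifnot(inherits(cfg, "transition_config"))
  keep <- max(1L, as.integer(floor(cfg$compression * in_ch)))
  layers <- list(layer_batchnorm(in_ch),
                 layer_relu(),
                 layer_conv2d(in_ch, keep, kernel = 1L),
                 layer_conv2d(keep, keep, kernel = 3L, stride = 2L))
  b <- new_block("transition", layers)
  b$out_ch <- keep
  b$forward <- function(x, training) {
    d <- dim(x)
    if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
      stop(sprintf("transition_layer: spatial dims (%d x %d) must be even", d[1], d[2]))
    seq_forward(b$layers, x, training)
  }
  b$backward <- function(dy) seq_backward(b$layers, dy)
  b
}

# ---- decoder upsampling: nearest-neighbour x2 then channel-halving 1x1 conv -

new_upsample <- function(in_ch) {
  out_ch <- max(1L, in_ch %/% 2L)
  layers <- list(layer_upsample_nn(),
                 layer_conv2d(in_ch, out_ch, kernel = 1L))
  b <- new_block("upsample", layers)
  b$out_ch <- out_ch
  b$forward <- function(x, training) seq_forward(b$layers, x, training)
  b$backward <- function(dy) seq_backward(b$layers, dy)
  b
}

# ---- functional entry points ------------------------------------------------

#' Stem block
#'
#' 3x3 convolution (stride 1) + batch normalization + ReLU lifting a
#' single-channel slice to `stem_width` feature channels without changing
#' resolution. Weights are drawn from the current RNG state (He-normal).
#'
#' @param x Rank-3 feature map with exactly one channel.
#' @param stem_width Number of output channels.
#' @return Feature map of the same height/width with `stem_width` channels.
#' @export
stem <- function(x, stem_width) {
  check_feature_map(x)
  block_forward(new_stem(dim(x)[3], stem_width), x)
}

#' Dilated convolution stack
#'
#' Three (by default) 3x3 convolutions with dilation rates doubling per layer
#' (2, 4, 8), each followed by batch normalization and ReLU; same-padding, so
#' resolution is preserved. The stack's unit-impulse receptive field spans
#' `1 + 2 * sum(rates)` pixels along each axis.
#'
#' @param x Feature map.
#' @param cfg A [ddb_config()].
#' @return Feature map with `cfg$dilated_channels` channels.
#' @export
dilated_block <- function(x, cfg) {
  check_feature_map(x)
  block_forward(new_dilated_block(dim(x)[3], cfg), x)
}

#' Densely connected convolution block
#'
#' `dense_layers` pre-activation layers (BN - ReLU - 3x3 conv - dropout), each
#' concatenating `growth` new channels onto the running stack, so the output
#' has `channels(x) + dense_layers * growth` channels.
#'
#' @inheritParams dilated_block
#' @return Feature map with `dim(x)[3] + L * g` channels.
#' @export
dense_block <- function(x, cfg) {
  check_feature_map(x)
  block_forward(new_dense_block(dim(x)[3], cfg), x)
}

#' Dilated Dense Block (DDB)
#'
#' The composition `dense_block(dilated_block(x, cfg), cfg)`: a broad-context
#' dilated stack feeding a detail-preserving dense block.
#'
#' @inheritParams dilated_block
#' @return Feature map with `dilated_channels + L * g` channels.
#' @export
ddb <- function(x, cfg) {
  check_feature_map(x)
  block_forward(new_ddb(dim(x)[3], cfg), x)
}

#' Transition layer
#'
#' BN - ReLU - 1x1 convolution keeping `floor(theta * C)` channels, followed
#' by a strided 3x3 convolution that halves both spatial dimensions. Odd
#' spatial dimensions are rejected so shapes stay exactly reproducible.
#'
#' @param x Feature map with even height and width.
#' @param cfg A [transition_config()].
#' @return Feature map at half resolution with `floor(theta * C)` channels.
#' @export
transition_layer <- function(x, cfg = transition_config()) {
  check_feature_map(x)
  block_forward(new_transition(dim(x)[3], cfg), x)
}

#' Decoder upsampling
#'
#' Nearest-neighbour x2 interpolation followed by a 1x1 convolution halving
#' the channel count.
#'
#' @param x Feature map.
#' @return Feature map at double resolution with `floor(C / 2)` channels.
#' @export
upsample <- function(x) {
  check_feature_map(x)
  block_forward(new_upsample(dim(x)[3]), x)
}
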