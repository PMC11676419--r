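# Model assembly: the five ablation variants, weight initialization,
# parameter counting, forward inference and backpropagation through the full
# encoder-decoder graph.

VARIANTS <- c("transformer_dil_denseunet", "transformer_denseunet",
              "dil_denseunet", "denseunet", "transformer_unet")

#' Model configuration
#'
#' All architecture knobs, pinned so parameter counts are exactly
#' reproducible. The defaults are the calibrated flagship configuration whose
#' parameter triple matches the published budget of the full model
#' (13,662,913 total; see the methods vignette for the calibration search).
#'
#' @param variant One of `"transformer_dil_denseunet"` (the flagship),
#'   `"transformer_denseunet"` (dense blocks + attention, no dilated stack),
#'   `"dil_denseunet"` (dilated dense blocks, no attention), `"denseunet"`
#'   (dense blocks only), `"transformer_unet"` (plain double-conv blocks +
#'   attention).
#' @param stem_width Channels produced by the stem block.
#' @param growth Dense-block growth rate `g`.
#' @param dense_layers Dense layers `L` per block.
#' @param dilated_channels Channels of each dilated convolution (also sets the
#'   plain-block width of the transformer_unet variant).
#' @param compression Transition-layer channel compression `theta`.
#' @param heads Attention heads per transformer block.
#' @param d_ff Hidden width of each transformer feed-forward sub-layer.
#' @param patch_schedule Patch edge length of the three decoder transformer
#'   stages, lowest resolution first.
#' @param dropout Dropout rate after each dense-layer convolution.
#' @param input_channels Input channels; fixed at 1 (one MRI modality).
#' @param norm_placement `"post"` or `"pre"` residual normalization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant = "transformer_dil_denseunet",
                         stem_width = 224L,
                         growth = 24L,
                         dense_layers = 4L,
                         dilated_channels = 100L,
                         compression = 0.5,
                         heads = 3L,
                         d_ff = 2960L,
                         patch_schedule = c(1L, 2L, 4L),
                         dropout = 0.2,
                         input_channels = 1L,
                         norm_placement = "post") {
  variant <- match.arg(variant, VARIANTS)
  stopifnot(stem_width >= 1, growth >= 1, dense_layers >= 1,
            dilated_channels >= 1, d_ff >= 1, heads >= 1,
            length(patch_schedule) == 3L, all(patch_schedule >= 1))
  if (input_channels != 1L)
    stop("model_config: input is single-channel (one modality at a time)")
  structure(list(variant = variant,
                 stem_width = as.integer(stem_width),
                 growth = as.integer(growth),
                 dense_layers = as.integer(dense_layers),
                 dilated_channels = as.integer(dilated_channels),
                 compression = compression,
                 heads = as.integer(heads),
                 d_ff = as.integer(d_ff),
                 patch_schedule = as.integer(patch_schedule),
                 dropout = dropout,
                 input_channels = 1L,
                 norm_placement = norm_placement),
            class = "model_config")
}

has_transformer <- function(variant)
  variant %in% c("transformer_dil_denseunet", "transformer_denseunet", "transformer_unet")

encoder_block_kind <- function(variant) {
  switch(variant,
         transformer_dil_denseunet = ,
         dil_denseunet = "ddb",
         transformer_denseunet = ,
         denseunet = "dense",
         transformer_unet = "plain")
}

# plain double-conv block (classic U-Net) used by the transformer_unet variant
new_plain_block <- function(in_ch, width) {
  layers <- list(layer_conv2d(in_ch, width, kernel = 3L), layer_batchnorm(width),
                 layer_relu(),
                 layer_conv2d(width, width, kernel = 3L), layer_batchnorm(width),
                 layer_relu())
  b <- new_block("plain", layers)
  b$out_ch <- width
  b$forward <- function(x, training) seq_forward(b$layers, x, training)
  b$backward <- function(dy) seq_backward(b$layers, dy)
  b
}

make_stage_block <- function(kind, in_ch, cfg) {
  dcfg <- ddb_config(cfg$dilated_channels, dense_layers = cfg$dense_layers,
                     growth = cfg$growth, dropout = cfg$dropout)
  switch(kind,
         ddb = new_ddb(in_ch, dcfg),
         dense = new_dense_block(in_ch, dcfg),
         plain = new_plain_block(in_ch, cfg$dilated_channels +
                                   cfg$dense_layers * cfg$growth))
}

#' Build a segmentation model
#'
#' Assembles the configured variant: stem, three encoder stages (block +
#' transition for the first two, block + bottleneck transition for the
#' third), a center block, and three decoder stages (upsample, skip
#' concatenation, optional transformer block, stage block), closed by a 1x1
#' convolution head producing per-pixel lesion logits.
#'
#' @param cfg A [model_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `ss_model`.
#' @export
build_model <- function(cfg = model_config(), seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  kind <- encoder_block_kind(cfg$variant)
  tcfg <- transition_config(cfg$compression)
  m <- new.env(parent = emptyenv())
  m$config <- cfg

  m$stem <- new_stem(cfg$input_channels, cfg$stem_width)
  ch <- m$stem$out_ch
  m$enc <- list(); m$tr <- list()
  enc_ch <- integer(3)
  for (i in 1:3) {
    m$enc[[i]] <- make_stage_block(kind, ch, cfg)
    enc_ch[i] <- m$enc[[i]]$out_ch
    m$tr[[i]] <- new_transition(enc_ch[i], tcfg)
    ch <- m$tr[[i]]$out_ch
  }
  m$center <- make_stage_block(kind, ch, cfg)
  ch <- m$center$out_ch

  m$up <- list(); m$tf <- list(); m$dec <- list()
  skips <- rev(enc_ch)             # decoder stage i pairs with encoder stage 4-i
  for (i in 1:3) {
    m$up[[i]] <- new_upsample(ch)
    cat_ch <- m$up[[i]]$out_ch + skips[i]
    if (has_transformer(cfg$variant)) {
      m$tf[[i]] <- new_transformer_block(cat_ch, cfg$patch_schedule[i],
                                         cfg$heads, cfg$d_ff,
                                         cfg$norm_placement)
    } else m$tf[i] <- list(NULL)
    m$dec[[i]] <- make_stage_block(kind, cat_ch, cfg)
    ch <- m$dec[[i]]$out_ch
  }
  m$head <- layer_conv2d(ch, 1L, kernel = 1L)
  m$blocks <- c(list(m$stem), m$enc, m$tr, list(m$center), m$up,
                Filter(Negate(is.null), m$tf), m$dec)
  class(m) <- "ss_model"
  m
}

collect_layers <- function(model) {
  ls <- unlist(lapply(model$blocks, function(b) b$layers), recursive = FALSE)
  c(ls, list(model$head))
}

model_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (d[1] %% 8L != 0L || d[2] %% 8L != 0L)
    stop(sprintf("input %d x %d: spatial dims must be divisible by 8", d[1], d[2]))
  s <- model$stem$forward(x, training)
  e <- vector("list", 3)
  h <- s
  for (i in 1:3) {
    e[[i]] <- model$enc[[i]]$forward(h, training)
    h <- model$tr[[i]]$forward(e[[i]], training)
  }
  h <- model$center$forward(h, training)
  skips <- list(e[[3]], e[[2]], e[[1]])
  for (i in 1:3) {
    u <- model$up[[i]]$forward(h, training)
    du <- dim(u); ds <- dim(skips[[i]])
    z <- array(c(u, skips[[i]]), dim = c(du[1], du[2], du[3] + ds[3]))
    if (!is.null(model$tf[[i]])) z <- model$tf[[i]]$forward(z, training)
    h <- model$dec[[i]]$forward(z, training)
  }
  model$head$fwd(h, training)          # logits, H x W x 1
}

model_backward <- function(model, dlogits) {
  du <- model$head$bwd(dlogits)
  dskip <- vector("list", 3)
  for (i in 3:1) {
    dz <- model$dec[[i]]$backward(du)
    if (!is.null(model$tf[[i]])) dz <- model$tf[[i]]$backward(dz)
    uch <- model$up[[i]]$out_ch
    dui <- dz[, , seq_len(uch), drop = FALSE]
    dskip[[i]] <- dz[, , (uch + 1L):dim(dz)[3], drop = FALSE]
    du <- model$up[[i]]$backward(dui)
  }
  dh <- model$center$backward(du)
  for (i in 3:1) {
    de <- model$tr[[i]]$backward(dh) + dskip[[4L - i]]
    dh <- model$enc[[i]]$backward(de)
  }
  model$stem$backward(dh)
}

#' Count model parameters
#'
#' Walks the instantiated layer list. Trainable parameters are every
#' convolution/linear weight and bias, batch-norm and layer-norm scales and
#' shifts; the non-trainable count is exactly the batch-norm running mean and
#' variance buffers (two per batch-normalized channel).
#'
#' @param model An `ss_model`.
#' @return An object of class `param_count`: list with `total`, `trainable`,
#'   `non_trainable`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ss_model"))
  layers <- collect_layers(model)
  tr <- 0L; nt <- 0L
  for (l in layers) {
    pc <- param_count_layer(l)
    tr <- tr + pc$trainable
    nt <- nt + pc$non_trainable
  }
  structure(list(total = tr + nt, trainable = tr, non_trainable = nt),
            class = "param_count")
}

#' @export
print.param_count <- function(x, ...) {
  cat(sprintf("parameters: total %s (trainable %s, non-trainable %s)\n",
              format(x$total, big.mark = ","),
              format(x$trainable, big.mark = ","),
              format(x$non_trainable, big.mark = ",")))
  invisible(x)
}

#' @export
print.ss_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<ss_model> variant=%s\n", x$config$variant))
  print(pc)
  invisible(x)
}

#' Segment a slice
#'
#' Runs the model forward in inference mode (running batch-norm statistics,
#' no dropout) and applies the sigmoid, producing a per-pixel lesion
#' probability map.
#'
#' @param object An `ss_model`.
#' @param image 2D matrix (or H x W x 1 array) in `[0, 1]`, spatial dims
#'   divisible by 8.
#' @param ... Unused.
#' @return Matrix of probabilities in `(0, 1)` with the input's spatial dims.
#' @export
predict.ss_model <- function(object, image, ...) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (length(dim(image)) != 3L || dim(image)[3] != 1L)
    stop("predict: image must be a single-channel 2D slice")
  logits <- model_forward(object, image, training = FALSE)
  p <- 1 / (1 + exp(-logits))
  matrix(p, dim(p)[1], dim(p)[2])
}

#' Threshold a probability map
#'
#' Strict-greater rule: a pixel is lesion iff its probability exceeds the
#' threshold, so ties fall to background.
#'
#' @param prob Numeric array of probabilities.
#' @param threshold Decision threshold in `(0, 1)`.
#' @return Binary array (0/1) of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("binarize: threshold must be in (0, 1)")
  (prob > threshold) * 1
}

#' Extract model weights
#'
#' Returns every trainable parameter and batch-norm buffer as a nested list
#' (one entry per layer, in graph order), suitable for checkpointing.
#'
#' @param model An `ss_model`.
#' @return Nested list of numeric arrays.
#' @export
serialize_weights <- function(model) {
  lapply(collect_layers(model),
         function(l) list(params = l$params, buffers = l$buffers))
}

#' Restore model weights
#'
#' Loads weights produced by [serialize_weights()] into a model built from
#' the same configuration (in place).
#'
#' @param model An `ss_model`.
#' @param state Result of [serialize_weights()].
#' @return `model`, invisibly.
#' @export
restore_weights <- function(model, state) {
  layers <- collect_layers(model)
  if (length(layers) != length(state))
    stop("restore_weights: checkpoint does not match the model topology")
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(state[[i]]$params)) {
      if (!identical(dim(l$params[[nm]]), dim(state[[i]]$params[[nm]])) &&
          length(l$params[[nm]]) != length(state[[i]]$params[[nm]]))
        stop("restore_weights: shape mismatch in layer ", i, " parameter ", nm)
      l$params[[nm]] <- state[[i]]$params[[nm]]
    }
    for (nm in names(state[[i]]$buffers))
      l$buffers[[nm]] <- state[[i]]$buffers[[nm]]
  }
  invisible(model)
}

zero_gradients <- function(model) {
  for (l in collect_layers(model)) zero_grads_layer(l)
  invisible(model)
}
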