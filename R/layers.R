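# Low-level differentiable layers. Each layer is an environment of class
# "ss_layer" holding parameter arrays, their gradients, optional non-trainable
# buffers (batch-norm running statistics), and closures fwd(x, training) /
# bwd(dy). Environments give the reference semantics needed for in-place
# optimizer updates.

new_layer <- function(type) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- list()    # named list of numeric arrays (trainable)
  l$grads <- list()     # same names, accumulated gradients
  l$buffers <- list()   # named list of non-trainable arrays
  class(l) <- "ss_layer"
  l
}

param_count_layer <- function(l) {
  list(trainable = sum(vapply(l$params, length, 0L)),
       non_trainable = sum(vapply(l$buffers, length, 0L)))
}

zero_grads_layer <- function(l) {
  l$grads <- lapply(l$params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  invisible(l)
}

#' He-normal truncated weight initialization
#'
#' Draws weights from a normal distribution with mean zero and standard
#' deviation \eqn{\sigma = \sqrt{2/m}} (where `m` is the fan-in, the number of
#' input units feeding the weight tensor), truncated at two standard
#' deviations: draws outside \eqn{\pm 2\sigma} are redrawn. This is the
#' classic He initialization for ReLU networks in its truncated form; it is
#' applied to every convolution and linear weight in the package's models.
#'
#' @param fan_in Positive integer, number of input units (`m`).
#' @param shape Integer vector, dimensions of the returned array.
#' @return Numeric array of dimension `shape` (a plain vector if `shape` has
#'   length 1), reproducible under `set.seed()`.
#' @examples
#' set.seed(1)
#' w <- he_normal_init(8, c(3, 3, 8, 4))   # sigma = 0.5
#' max(abs(w)) <= 1
#' @export
he_normal_init <- function(fan_in, shape) {
  if (length(fan_in) != 1L || !is.finite(fan_in) || fan_in < 1)
    stop("he_normal_init: fan_in must be a positive integer")
  sigma <- sqrt(2 / fan_in)
  n <- prod(shape)
  x <- stats::rnorm(n, 0, sigma)
  bad <- which(abs(x) > 2 * sigma)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), 0, sigma)
    bad <- bad[abs(x[bad]) > 2 * sigma]
  }
  if (length(shape) > 1L) array(x, dim = shape) else x
}

# ---- convolution ------------------------------------------------------------

layer_conv2d <- function(in_ch, out_ch, kernel = 3L, stride = 1L, dilation = 1L) {
  l <- new_layer("conv2d")
  l$in_ch <- in_ch; l$out_ch <- out_ch
  l$kernel <- as.integer(kernel); l$stride <- as.integer(stride)
  l$dilation <- as.integer(dilation)
  fan_in <- kernel * kernel * in_ch
  l$params$W <- he_normal_init(fan_in, c(kernel, kernel, in_ch, out_ch))
  l$params$b <- numeric(out_ch)
  l$fwd <- function(x, training = FALSE) {
    if (dim(x)[3] != l$in_ch)
      stop(sprintf("conv2d: expected %d input channels, got %d", l$in_ch, dim(x)[3]))
    if (training) l$cache_x <- x
    conv2d_fwd(x, l$params$W, l$params$b, l$stride, l$dilation)
  }
  l$bwd <- function(dy) {
    g <- conv2d_bwd(l$cache_x, l$params$W, dy, l$stride, l$dilation)
    l$grads$W <- l$grads$W + g$dw
    l$grads$b <- l$grads$b + as.numeric(g$db)
    l$cache_x <- NULL
    g$dx
  }
  zero_grads_layer(l)
  l
}

# ---- batch normalization ----------------------------------------------------

# Normalizes each channel over the spatial dimensions of the sample being
# processed (maps are rank-3; minibatches are handled upstream by gradient
# accumulation). Running statistics follow the usual exponential moving
# average and are the model's only non-trainable parameters.
layer_batchnorm <- function(ch, momentum = 0.99, eps = 1e-3) {
  l <- new_layer("batchnorm")
  l$ch <- ch; l$momentum <- momentum; l$eps <- eps
  l$params$gamma <- rep(1, ch)
  l$params$beta <- rep(0, ch)
  l$buffers$running_mean <- rep(0, ch)
  l$buffers$running_var <- rep(1, ch)
  l$fwd <- function(x, training = FALSE) {
    d <- dim(x); m <- d[1] * d[2]
    xm <- matrix(x, m, d[3])
    if (training) {
      mu <- colMeans(xm)
      v <- colMeans(xm^2) - mu^2
      v[v < 0] <- 0
      l$buffers$running_mean <- l$momentum * l$buffers$running_mean + (1 - l$momentum) * mu
      l$buffers$running_var <- l$momentum * l$buffers$running_var + (1 - l$momentum) * v
    } else {
      mu <- l$buffers$running_mean
      v <- l$buffers$running_var
    }
    inv <- 1 / sqrt(v + l$eps)
    xhat <- (xm - rep(mu, each = m)) * rep(inv, each = m)
    y <- xhat * rep(l$params$gamma, each = m) + rep(l$params$beta, each = m)
    if (training) {
      l$cache <- list(xhat = xhat, inv = inv, m = m, d = d, training = TRUE)
    }
    array(y, dim = d)
  }
  l$bwd <- function(dy) {
    cc <- l$cache; m <- cc$m; d <- cc$d
    dym <- matrix(dy, m, d[3])
    l$grads$gamma <- l$grads$gamma + colSums(dym * cc$xhat)
    l$grads$beta <- l$grads$beta + colSums(dym)
    dxhat <- dym * rep(l$params$gamma, each = m)
    # batch statistics were used in the forward pass: full BN backward
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cc$xhat)
    dxm <- (dxhat - rep(s1 / m, each = m) - cc$xhat * rep(s2 / m, each = m)) *
      rep(cc$inv, each = m)
    l$cache <- NULL
    array(dxm, dim = d)
  }
  zero_grads_layer(l)
  l
}

# ---- simple activations -----------------------------------------------------

layer_relu <- function() {
  l <- new_layer("relu")
  l$fwd <- function(x, training = FALSE) {
    y <- x * (x > 0)
    if (training) l$cache <- (x > 0)
    y
  }
  l$bwd <- function(dy) {
    dx <- dy * l$cache
    l$cache <- NULL
    dx
  }
  l
}

layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  l <- new_layer("dropout")
  l$rate <- rate
  l$fwd <- function(x, training = FALSE) {
    if (!training || l$rate == 0) return(x)
    keep <- 1 - l$rate
    mask <- array(stats::rbinom(length(x), 1L, keep) / keep, dim = dim(x))
    l$cache <- mask
    x * mask
  }
  l$bwd <- function(dy) {
    if (is.null(l$cache)) return(dy)
    dx <- dy * l$cache
    l$cache <- NULL
    dx
  }
  l
}

# ---- nearest-neighbour upsampling x2 ---------------------------------------

layer_upsample_nn <- function() {
  l <- new_layer("upsample_nn")
  l$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    idx_h <- rep(seq_len(d[1]), each = 2L)
    idx_w <- rep(seq_len(d[2]), each = 2L)
    x[idx_h, idx_w, , drop = FALSE]
  }
  l$bwd <- function(dy) {
    d <- dim(dy)
    h <- d[1] / 2L; w <- d[2] / 2L
    dx <- array(0, dim = c(h, w, d[3]))
    for (a in 1:2) for (b in 1:2) {
      dx <- dx + dy[seq(a, d[1], by = 2L), seq(b, d[2], by = 2L), , drop = FALSE]
    }
    dx
  }
  l
}

# ---- dense (linear) layer on token matrices --------------------------------

layer_linear <- function(in_dim, out_dim) {
  l <- new_layer("linear")
  l$in_dim <- in_dim; l$out_dim <- out_dim
  l$params$W <- he_normal_init(in_dim, c(in_dim, out_dim))
  l$params$b <- numeric(out_dim)
  l$fwd <- function(x, training = FALSE) {
    if (training) l$cache_x <- x
    sweep(x %*% l$params$W, 2L, l$params$b, "+")
  }
  l$bwd <- function(dy) {
    l$grads$W <- l$grads$W + crossprod(l$cache_x, dy)
    l$grads$b <- l$grads$b + colSums(dy)
    dx <- tcrossprod(dy, l$params$W)
    l$cache_x <- NULL
    dx
  }
  zero_grads_layer(l)
  l
}

# ---- layer normalization (per token, over the embedding dimension) ---------

layer_layernorm <- function(dim, eps = 1e-5) {
  l <- new_layer("layernorm")
  l$dim <- dim; l$eps <- eps
  l$params$gamma <- rep(1, dim)
  l$params$beta <- rep(0, dim)
  l$fwd <- function(x, training = FALSE) {
    mu <- rowMeans(x)
    v <- rowMeans(x^2) - mu^2
    v[v < 0] <- 0
    inv <- 1 / sqrt(v + l$eps)
    xhat <- (x - mu) * inv
    if (training) l$cache <- list(xhat = xhat, inv = inv)
    sweep(sweep(xhat, 2L, l$params$gamma, "*"), 2L, l$params$beta, "+")
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    n <- ncol(dy)
    dxhat <- sweep(dy, 2L, l$params$gamma, "*")
    l$grads$gamma <- l$grads$gamma + colSums(dy * cc$xhat)
    l$grads$beta <- l$grads$beta + colSums(dy)
    s1 <- rowSums(dxhat) / n
    s2 <- rowSums(dxhat * cc$xhat) / n
    dx <- (dxhat - s1 - cc$xhat * s2) * cc$inv
    l$cache <- NULL
    dx
  }
  zero_grads_layer(l)
  l
}
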