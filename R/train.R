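# Training loop (Adam, minibatch by gradient accumulation) and evaluation.

#' Run configuration
#'
#' Bundles the training hyper-parameters with their published defaults:
#' 3x3 kernels, batch size 8, ReLU activations, dropout 0.2, learning rate
#' 1e-4, Adam, 100 epochs, BCE-Dice loss. Every field can be overridden.
#'
#' @param variant Model variant, see [model_config()].
#' @param loss One of `"bce"`, `"dice"`, `"sigmoid_bce"`, `"bce_dice"`.
#' @param epochs Training epochs.
#' @param batch_size Gradient-accumulation batch size.
#' @param learning_rate Adam step size.
#' @param dropout Dropout rate.
#' @param seed RNG seed recorded with the run.
#' @param threshold Binarization threshold for the Dice/accuracy logs.
#' @return Object of class `run_config`.
#' @export
run_config <- function(variant = "transformer_dil_denseunet",
                       loss = "bce_dice", epochs = 100L, batch_size = 8L,
                       learning_rate = 1e-4, dropout = 0.2, seed = 1L,
                       threshold = 0.5) {
  loss <- match.arg(loss, c("bce", "dice", "sigmoid_bce", "bce_dice"))
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(variant = variant, loss = loss, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout = dropout,
                 seed = as.integer(seed), threshold = threshold,
                 kernel = 3L, optimizer = "adam", activation = "relu"),
            class = "run_config")
}

adam_update <- function(model, state, lr, batch_n,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in collect_layers(model)) {
    if (!length(l$params)) next
    if (is.null(l$opt)) {
      l$opt <- lapply(l$params, function(p) list(m = p * 0, v = p * 0))
    }
    for (nm in names(l$params)) {
      g <- l$grads[[nm]] / batch_n
      st <- l$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      l$opt[[nm]] <- st
      l$params[[nm]] <- l$params[[nm]] - lr * (st$m / c1) / (sqrt(st$v / c2) + eps)
    }
  }
  invisible(NULL)
}

#' Train a segmentation model
#'
#' Seeded minibatch training with Adam. Each epoch shuffles the pairs,
#' accumulates gradients over `batch_size` slices per update, and logs the
#' mean training loss plus train (and optionally validation) Dice and
#' accuracy computed from binarized predictions.
#'
#' @param model An `ss_model` (modified in place).
#' @param pairs List of [slice_pair()] training data.
#' @param val_pairs Optional validation pairs.
#' @param loss Loss name: `"bce"`, `"dice"`, `"sigmoid_bce"` or `"bce_dice"`.
#' @param epochs Number of epochs.
#' @param batch_size Slices per optimizer step (gradient accumulation).
#' @param learning_rate Adam step size.
#' @param seed Optional seed fixing shuffling and dropout.
#' @param verbose Print a line per epoch.
#' @return Data frame history: one row per epoch with `loss`, `dice`,
#'   `accuracy` and, when validation pairs are given, `val_dice`,
#'   `val_accuracy`.
#' @export
train_model <- function(model, pairs, val_pairs = NULL, loss = "bce_dice",
                        epochs = 5L, batch_size = 8L, learning_rate = 1e-4,
                        seed = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "ss_model"), length(pairs) >= 1)
  loss <- match.arg(loss, c("bce", "dice", "sigmoid_bce", "bce_dice"))
  if (!is.null(seed)) set.seed(seed)
  state <- new.env(); state$t <- 0L
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(pairs))
    zero_gradients(model)
    nacc <- 0L
    losses <- numeric(0)
    cc <- list(TP = 0, TN = 0, FP = 0, FN = 0)
    for (i in ord) {
      p <- pairs[[i]]
      x <- array(p$image, dim = c(dim(p$image), 1L))
      z <- model_forward(model, x, training = TRUE)
      y <- array(p$mask, dim = dim(z))
      lv <- loss_value(loss, y, z)
      if (!is.finite(lv))
        stop(sprintf("training aborted: non-finite %s loss at epoch %d", loss, ep))
      losses <- c(losses, lv)
      pred <- binarize(1 / (1 + exp(-z)))
      cf <- confusion(y, pred)
      for (nm in names(cc)) cc[[nm]] <- cc[[nm]] + cf[[nm]]
      dz <- array(loss_gradient(loss, y, z), dim = dim(z))
      model_backward(model, dz)
      nacc <- nacc + 1L
      if (nacc == batch_size) {
        adam_update(model, state, learning_rate, nacc)
        zero_gradients(model)
        nacc <- 0L
      }
    }
    if (nacc > 0L) {
      adam_update(model, state, learning_rate, nacc)
      zero_gradients(model)
    }
    class(cc) <- "confusion_counts"
    row <- data.frame(epoch = ep, loss = mean(losses),
                      dice = dice_coefficient(cc), accuracy = accuracy(cc))
    if (!is.null(val_pairs)) {
      ev <- evaluate_model(model, val_pairs)
      row$val_dice <- ev$mean_dice
      row$val_accuracy <- ev$mean_accuracy
    }
    hist[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  dice %.3f", ep, epochs,
                      row$loss, row$dice))
  }
  do.call(rbind, hist)
}

#' Evaluate a model on slice pairs
#'
#' @param model An `ss_model`.
#' @param pairs List of slice pairs.
#' @param threshold Binarization threshold.
#' @return Object of class `ss_evaluation`: list with `per_slice` (data frame
#'   of per-slice Dice and accuracy) and the means `mean_dice`,
#'   `mean_accuracy`.
#' @export
evaluate_model <- function(model, pairs, threshold = 0.5) {
  stopifnot(inherits(model, "ss_model"), length(pairs) >= 1)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    prob <- predict(model, p$image)
    cf <- confusion(p$mask, binarize(prob, threshold))
    data.frame(index = i, subject = p$subject, slice = p$slice,
               dice = dice_coefficient(cf), accuracy = accuracy(cf))
  })
  per <- do.call(rbind, rows)
  structure(list(per_slice = per, mean_dice = mean(per$dice),
                 mean_accuracy = mean(per$accuracy)),
            class = "ss_evaluation")
}

#' @export
print.ss_evaluation <- function(x, ...) {
  cat(sprintf("evaluation over %d slices: mean Dice %.4f, mean accuracy %.4f\n",
              nrow(x$per_slice), x$mean_dice, x$mean_accuracy))
  invisible(x)
}
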