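# Training losses and evaluation metrics. All losses reduce by the mean over
# pixels, are non-negative, and operate on a ground-truth binary mask `y` and
# a prediction of the same shape (probabilities, or logits for the
# sigmoid-BCE form).

EPS_PROB <- 1e-7

check_pair <- function(y, yhat) {
  if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat))
    stop("mask pair: y and yhat must have identical shapes")
  if (any(y != 0 & y != 1)) stop("mask pair: y must be binary")
  invisible(NULL)
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-[y log p + (1-y) log(1-p)]`, with probabilities
#' clipped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param y Binary ground-truth mask.
#' @param yhat Predicted probabilities in `[0, 1]`, same shape.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y, yhat) {
  check_pair(y, yhat)
  p <- pmin(pmax(yhat, EPS_PROB), 1 - EPS_PROB)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Soft Dice loss
#'
#' `1 - (2 sum(y p) + s) / (sum(y) + sum(p) + s)` with smoothing `s`
#' (default 1), which rewards overlap between the predicted soft mask and the
#' ground truth and is robust to the heavy lesion/background class imbalance.
#'
#' @inheritParams bce_loss
#' @param smooth Smoothing constant protecting the empty-mask case.
#' @return Scalar in `[0, 1)`.
#' @export
dice_loss <- function(y, yhat, smooth = 1) {
  check_pair(y, yhat)
  1 - (2 * sum(y * yhat) + smooth) / (sum(y) + sum(yhat) + smooth)
}

#' Sigmoid binary cross-entropy (on logits)
#'
#' Numerically stable form of `bce_loss(y, sigmoid(logits))`:
#' `mean(max(z, 0) - z y + log(1 + exp(-|z|)))`.
#'
#' @param y Binary ground-truth mask.
#' @param logits Real-valued scores, same shape as `y`.
#' @return Non-negative scalar.
#' @export
sigmoid_bce_loss <- function(y, logits) {
  check_pair(y, logits * 0)   # shape check only
  z <- logits
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

#' Combined BCE-Dice loss
#'
#' The unit-weight sum [bce_loss()] + [dice_loss()], coupling pixel-wise
#' classification accuracy with region overlap; the default training loss.
#'
#' @inheritParams dice_loss
#' @return Non-negative scalar.
#' @export
bce_dice_loss <- function(y, yhat, smooth = 1) {
  bce_loss(y, yhat) + dice_loss(y, yhat, smooth)
}

#' Confusion counts of a binary segmentation
#'
#' @param y Binary ground-truth mask.
#' @param pred Binary predicted mask, same shape.
#' @return Object of class `confusion_counts`: list `TP`, `TN`, `FP`, `FN`
#'   with `TP + TN + FP + FN` equal to the pixel count.
#' @export
confusion <- function(y, pred) {
  if (!identical(dim(y), dim(pred)) || length(y) != length(pred))
    stop("confusion: shapes differ")
  if (any(y != 0 & y != 1) || any(pred != 0 & pred != 1))
    stop("confusion: inputs must be binary")
  structure(list(TP = sum(y == 1 & pred == 1),
                 TN = sum(y == 0 & pred == 0),
                 FP = sum(y == 0 & pred == 1),
                 FN = sum(y == 1 & pred == 0)),
            class = "confusion_counts")
}

#' Dice coefficient
#'
#' `2 TP / (2 TP + FP + FN)`. When prediction and ground truth are both empty
#' (TP = FP = FN = 0) the overlap is perfect by convention and 1 is returned.
#'
#' @param c A [confusion()] result.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  denom <- 2 * c$TP + c$FP + c$FN
  if (denom == 0) return(1)
  2 * c$TP / denom
}

#' Pixel accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param c A [confusion()] result.
#' @return Scalar in `[0, 1]`.
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  m <- c$TP + c$TN + c$FP + c$FN
  if (m == 0) stop("accuracy: empty masks")
  (c$TP + c$TN) / m
}

# gradient of each loss with respect to the model logits z (p = sigmoid(z));
# used by the training loop
loss_gradient <- function(name, y, z) {
  p <- 1 / (1 + exp(-z))
  m <- length(y)
  switch(name,
         bce = ,
         sigmoid_bce = (p - y) / m,
         dice = {
           s <- 1
           num <- 2 * sum(y * p) + s
           den <- sum(y) + sum(p) + s
           dp <- -(2 * y * den - num) / den^2
           dp * p * (1 - p)
         },
         bce_dice = {
           s <- 1
           num <- 2 * sum(y * p) + s
           den <- sum(y) + sum(p) + s
           dp <- -(2 * y * den - num) / den^2
           (p - y) / m + dp * p * (1 - p)
         },
         stop(sprintf("unknown loss '%s'", name)))
}

loss_value <- function(name, y, z) {
  p <- 1 / (1 + exp(-z))
  switch(name,
         bce = bce_loss(y, p),
         sigmoid_bce = sigmoid_bce_loss(y, z),
         dice = dice_loss(y, p),
         bce_dice = bce_dice_loss(y, p),
         stop(sprintf("unknown loss '%s'", name)))
}
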