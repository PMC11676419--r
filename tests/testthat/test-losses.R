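# The four training losses and the two evaluation metrics.

test_that("binary cross-entropy matches closed forms and the pixel-loop oracle", {
  y <- matrix(c(1, 0, 1, 0), 2)
  expect_lt(bce_loss(y, y), 1e-6)                      # perfect prediction
  expect_equal(bce_loss(matrix(1), matrix(0.5)), log(2), tolerance = 1e-12)
  set.seed(1)
  yr <- matrix(rbinom(24, 1, 0.4), 4)
  pr <- matrix(runif(24), 4)
  manual <- -mean(sapply(seq_along(yr), function(i)
    yr[i] * log(pr[i]) + (1 - yr[i]) * log(1 - pr[i])))
  expect_equal(bce_loss(yr, pr), manual, tolerance = 1e-9)
  expect_error(bce_loss(matrix(1), matrix(0.5, 2)), "shape")
})

test_that("soft Dice loss follows its formula including degenerate masks", {
  yk <- matrix(0, 20, 10); yk[1:100] <- 1                 # 100 positives
  expect_equal(dice_loss(yk, yk), 1 - 201 / 201)
  # disjoint masks, 50 positives each
  a <- matrix(0, 10, 10); a[1:50] <- 1
  b <- matrix(0, 10, 10); b[51:100] <- 1
  expect_equal(dice_loss(a, b), 1 - 1 / 101, tolerance = 1e-12)
  # both empty: smoothing prevents 0/0
  z <- matrix(0, 4, 4)
  expect_equal(dice_loss(z, z), 0)
  # converges to the hard-count Dice as smoothing vanishes
  set.seed(2)
  for (i in 1:10) {
    yr <- matrix(rbinom(36, 1, 0.5), 6)
    pr <- matrix(rbinom(36, 1, 0.5), 6)
    if (sum(yr) + sum(pr) == 0) next
    hard <- dice_coefficient(confusion(yr, pr))
    expect_equal(1 - dice_loss(yr, pr, smooth = 1e-8), hard, tolerance = 1e-6)
  }
})

test_that("sigmoid BCE is the stable composition of sigmoid and BCE", {
  expect_equal(sigmoid_bce_loss(matrix(1), matrix(0)), log(2), tolerance = 1e-12)
  expect_lt(sigmoid_bce_loss(matrix(1), matrix(50)), 1e-10)   # saturation
  set.seed(3)
  y <- matrix(rbinom(30, 1, 0.5), 5)
  z <- matrix(rnorm(30, sd = 3), 5)
  expect_equal(sigmoid_bce_loss(y, z), bce_loss(y, 1 / (1 + exp(-z))),
               tolerance = 1e-6)
})

test_that("BCE-Dice is exactly the sum of its parts and near zero when perfect", {
  set.seed(4)
  y <- matrix(rbinom(40, 1, 0.3), 5)
  p <- matrix(runif(40), 5)
  expect_identical(bce_dice_loss(y, p), bce_loss(y, p) + dice_loss(y, p))
  expect_lt(bce_dice_loss(y, y), 0.02)
  expect_gte(bce_loss(y, p), 0)
  expect_gte(dice_loss(y, p), 0)
})

test_that("confusion counts match exhaustive enumeration and hand cases", {
  cf <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cf)[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  # all 16 configurations of a 2-pixel pair against the loop oracle
  for (a in 0:1) for (b in 0:1) for (c in 0:1) for (d in 0:1) {
    y <- c(a, b); pred <- c(c, d)
    cf <- confusion(y, pred)
    or <- confusion_oracle(y, pred)
    expect_identical(c(TP = cf$TP, TN = cf$TN, FP = cf$FP, FN = cf$FN), or)
    expect_identical(cf$TP + cf$TN + cf$FP + cf$FN, 2L)
  }
  y <- matrix(rbinom(16, 1, 0.5), 4)
  expect_identical(confusion(y, y)$FP + confusion(y, y)$FN, 0L)
  expect_identical(confusion(y, 1 - y)$TP + confusion(y, 1 - y)$TN, 0L)
  expect_error(confusion(matrix(0.5), matrix(1)), "binary")
})

test_that("Dice and accuracy reproduce hand-computed values", {
  cf <- structure(list(TP = 1, TN = 1, FP = 1, FN = 1), class = "confusion_counts")
  expect_equal(dice_coefficient(cf), 0.5)
  expect_equal(accuracy(cf), 0.5)
  y <- matrix(rbinom(25, 1, 0.4), 5)
  expect_equal(dice_coefficient(confusion(y, y)), 1)
  expect_equal(accuracy(confusion(y, y)), 1)
  if (sum(y) > 0 && sum(1 - y) > 0) {
    expect_equal(dice_coefficient(confusion(y, 1 - y)), 0)
    expect_equal(accuracy(confusion(y, 1 - y)), 0)
  }
  # empty-vs-empty is perfect overlap by convention
  z <- matrix(0, 3, 3)
  expect_equal(dice_coefficient(confusion(z, z)), 1)
})

test_that("metrics are invariant to pixel permutation", {
  set.seed(5)
  y <- rbinom(50, 1, 0.3); p <- rbinom(50, 1, 0.3)
  perm <- sample(50)
  c1 <- confusion(y, p); c2 <- confusion(y[perm], p[perm])
  expect_equal(dice_coefficient(c1), dice_coefficient(c2))
  expect_equal(accuracy(c1), accuracy(c2))
  pp <- runif(50)   # loss permutation invariance
  expect_equal(bce_loss(y, pp), bce_loss(y[perm], pp[perm]))
  expect_equal(dice_loss(y, pp), dice_loss(y[perm], pp[perm]))
})
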