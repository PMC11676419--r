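# NIfTI I/O, slice extraction, blank trimming, resizing, normalization,
# paired augmentation and splitting.

test_that("NIfTI volumes round-trip with spacing preserved", {
  set.seed(1)
  vol <- strokeseg:::new_stroke_volume(array(runif(6 * 10 * 12), c(6, 10, 12)),
                                       subject = "sub-001",
                                       spacing = c(2, 1, 1.5))
  f <- tempfile(fileext = ".nii.gz")
  save_volume(vol, f)
  v2 <- load_volume(f)
  expect_equal(v2$data, vol$data, tolerance = 1e-7)
  expect_equal(v2$spacing, vol$spacing, tolerance = 1e-6)
  expect_error(load_volume(tempfile("missing_", fileext = ".nii")), "missing_")
  # truncated file raises an error naming the path
  bad <- tempfile("trunc_", fileext = ".nii")
  writeLines("not a nifti", bad)
  expect_error(load_volume(bad), "trunc_")
})

test_that("slice extraction preserves order, count and content", {
  arr <- array(seq_len(5 * 4 * 4), c(5, 4, 4))
  vol <- strokeseg:::new_stroke_volume(arr)
  sl <- extract_slices(vol)
  expect_length(sl, 5)
  expect_identical(sl[[3]], arr[3, , ])
  one <- strokeseg:::new_stroke_volume(array(1, c(1, 4, 4)))
  expect_length(extract_slices(one), 1)
})

test_that("blank-slice trimming removes only the ends", {
  mk <- function(fg) if (fg) matrix(runif(16, 0.5, 1), 4) else matrix(0, 4, 4)
  set.seed(2)
  imgs <- lapply(c(F, F, T, T, T, T, T, F, F, F), mk)
  msks <- lapply(1:10, function(i) matrix(0, 4, 4))
  tr <- remove_blank_slices(imgs, msks)
  expect_identical(tr$indices, 3:7)
  expect_length(tr$slices, 5)
  # interior blank retained
  imgs2 <- lapply(c(T, F, T), mk)
  tr2 <- remove_blank_slices(imgs2, msks[1:3])
  expect_identical(tr2$indices, 1:3)
  # untouched when nothing is blank
  imgs3 <- lapply(c(T, T), mk)
  expect_identical(remove_blank_slices(imgs3, msks[1:2])$indices, 1:2)
  expect_warning(tr4 <- remove_blank_slices(lapply(c(F, F), mk), msks[1:2]),
                 "blank")
  expect_length(tr4$slices, 0)
})

test_that("resizing hits the target grid and respects mask binarity", {
  set.seed(3)
  img <- matrix(runif(230 * 230), 230)
  out <- resize_slice(img, 192, "image")
  expect_identical(dim(out), c(192L, 192L))
  expect_equal(resize_slice(matrix(0.7, 20, 20), 8, "image"),
               matrix(0.7, 8, 8), tolerance = 1e-12)
  msk <- matrix(rbinom(230 * 230, 1, 0.1), 230)
  rm <- resize_slice(msk, 192, "mask")
  expect_true(all(rm %in% c(0, 1)))
  expect_error(resize_slice(array(1, c(4, 4, 2)), 8), "2D")
})

test_that("min-max normalization maps to [0,1] and handles constants", {
  expect_equal(normalize_slice(matrix(c(10, 20, 30, 10), 2)),
               matrix(c(0, 0.5, 1, 0), 2))
  already <- matrix(c(0, 0.25, 1, 0.5), 2)
  expect_equal(normalize_slice(already), already)
  expect_equal(normalize_slice(matrix(5, 3, 3)), matrix(0, 3, 3))
  expect_error(normalize_slice(matrix(c(1, NA), 1)), "finite")
})

test_that("augmentation multiplies counts, keeps pairing, and is seeded", {
  set.seed(4)
  p <- slice_pair(matrix(runif(64), 8), matrix(rbinom(64, 1, 0.3), 8),
                  subject = "s1", slice = 5L)
  a3 <- augment_pairs(list(p), factor = 3, seed = 11)
  expect_length(a3, 3)
  expect_identical(a3[[1]]$image, p$image)        # original kept
  expect_true(all(vapply(a3, function(q) all(q$mask %in% c(0, 1)), TRUE)))
  expect_true(all(vapply(a3, function(q) q$subject == "s1", TRUE)))
  b3 <- augment_pairs(list(p), factor = 3, seed = 11)
  expect_identical(lapply(a3, `[[`, "image"), lapply(b3, `[[`, "image"))
  many <- augment_pairs(rep(list(p), 10), factor = 3, seed = 12)
  expect_length(many, 30)
  # horizontal flip applied twice is the identity
  f <- strokeseg:::apply_transform(p$image, list(type = "flip", par = NA))
  expect_identical(strokeseg:::apply_transform(f, list(type = "flip", par = NA)),
                   p$image)
})

test_that("the split is an 80/20 seeded partition of the input", {
  ps <- lapply(1:100, function(i)
    slice_pair(matrix(i, 2, 2), matrix(0, 2, 2), slice = i))
  sp <- split_pairs(ps, 0.8, seed = 5)
  expect_length(sp$train, 80)
  expect_length(sp$validation, 20)
  got <- sort(vapply(c(sp$train, sp$validation), `[[`, 0L, "slice"))
  expect_identical(got, 1:100)                     # conservation, disjointness
  sp2 <- split_pairs(ps, 0.8, seed = 5)
  expect_identical(vapply(sp2$train, `[[`, 0L, "slice"),
                   vapply(sp$train, `[[`, 0L, "slice"))
  sp3 <- split_pairs(ps, 0.8, seed = 6)
  expect_false(identical(vapply(sp3$train, `[[`, 0L, "slice"),
                         vapply(sp$train, `[[`, 0L, "slice")))
  expect_error(split_pairs(ps[1], 0.8), "at least 2")
  expect_error(split_pairs(ps, 1.2), "train_frac")
})
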