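# Slice preprocessing pipeline: NIfTI volume loading, axial slice extraction,
# blank-slice trimming at the scan ends, resizing, min-max normalization,
# paired geometric augmentation and the train/validation split.

#' Load a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file and normalizes the axis order to depth-major
#' (slice, height, width), with voxel spacing preserved from the header.
#'
#' @param path Path to a NIfTI file.
#' @param subject Optional subject identifier (defaults to the file stem).
#' @param modality Optional modality tag (`"FLAIR"`, `"DWI"`, `"T1"`, `"T2"`).
#' @return An object of class `stroke_volume`: list with `subject`,
#'   `modality`, `data` (depth x height x width array) and `spacing` (mm).
#' @export
load_volume <- function(path, subject = NULL, modality = NULL) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("cannot read NIfTI volume '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  if (length(dim(arr)) != 3L)
    stop(sprintf("cannot read NIfTI volume '%s': expected a 3D image", path))
  sp <- RNifti::pixdim(img)
  if (is.null(subject)) subject <- sub("\\.nii(\\.gz)?$", "", basename(path))
  new_stroke_volume(aperm(arr, c(3L, 1L, 2L)), subject = subject,
                    modality = modality,
                    spacing = c(sp[3], sp[1], sp[2]))
}

#' Construct a volume object
#'
#' @param data Depth x height x width array of finite voxel values.
#' @param subject Subject identifier.
#' @param modality Optional modality tag.
#' @param spacing Voxel spacing in mm (depth, height, width).
#' @return An object of class `stroke_volume`.
#' @export
new_stroke_volume <- function(data, subject = "unknown", modality = NULL,
                              spacing = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3L)
  if (any(!is.finite(data))) stop("stroke_volume: voxel values must be finite")
  structure(list(subject = subject, modality = modality,
                 data = data, spacing = spacing),
            class = "stroke_volume")
}

#' Write a volume as NIfTI
#'
#' @param vol A `stroke_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "stroke_volume"))
  arr <- aperm(vol$data, c(2L, 3L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vol$spacing[2], vol$spacing[3], vol$spacing[1])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @export
print.stroke_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<stroke_volume> %s%s: %d slices of %d x %d, spacing %s mm\n",
              x$subject, if (is.null(x$modality)) "" else paste0(" [", x$modality, "]"),
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' Extract axial slices
#'
#' @param vol A `stroke_volume`.
#' @return List of 2D matrices, one per axial index, in order.
#' @export
extract_slices <- function(vol) {
  stopifnot(inherits(vol, "stroke_volume"))
  d <- dim(vol$data)
  lapply(seq_len(d[1]), function(k) vol$data[k, , ])
}

#' Trim blank slices from both ends of a scan
#'
#' A slice is blank when its foreground fraction (pixels brighter than 1% of
#' the slice maximum) falls below `fg_threshold`. Only leading and trailing
#' blank runs are removed; an interior blank slice is always retained, so the
#' kept indices form one contiguous range.
#'
#' @param slices List of image matrices.
#' @param masks Aligned list of mask matrices.
#' @param fg_threshold Minimum foreground fraction of a non-blank slice.
#' @param intensity_floor Foreground intensity floor as a fraction of the
#'   slice maximum.
#' @return List with `slices`, `masks` and the kept `indices`; empty (with a
#'   warning) when every slice is blank.
#' @export
remove_blank_slices <- function(slices, masks, fg_threshold = 0.02,
                                intensity_floor = 0.01) {
  stopifnot(length(slices) == length(masks))
  fg <- vapply(slices, function(s) {
    mx <- max(s)
    if (mx <= 0) return(0)
    mean(s > intensity_floor * mx)
  }, 0)
  keep <- which(fg >= fg_threshold)
  if (!length(keep)) {
    warning("remove_blank_slices: all slices are blank")
    return(list(slices = list(), masks = list(), indices = integer(0)))
  }
  idx <- keep[1]:keep[length(keep)]
  list(slices = slices[idx], masks = masks[idx], indices = idx)
}

#' Resize a slice
#'
#' Bilinear interpolation for images; nearest-neighbour for masks, so binary
#' masks stay binary.
#'
#' @param image 2D matrix.
#' @param target Output edge length in pixels (square output).
#' @param kind `"image"` or `"mask"`.
#' @return `target x target` matrix.
#' @export
resize_slice <- function(image, target = 192L, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (length(dim(image)) != 2L) stop("resize_slice: input must be 2D")
  filt <- if (kind == "image") "bilinear" else "none"
  out <- EBImage::resize(EBImage::Image(image), w = target, h = target,
                         filter = filt)
  matrix(EBImage::imageData(out), target, target)
}

#' Min-max normalize a slice to [0, 1]
#'
#' Per-slice scaling; a constant slice maps to all zeros.
#'
#' @param image 2D matrix of finite values.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_slice <- function(image) {
  if (any(!is.finite(image))) stop("normalize_slice: non-finite input")
  rng <- range(image)
  if (rng[2] <= rng[1]) return(image * 0)
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Construct a slice pair
#'
#' @param image 2D image in `[0, 1]`.
#' @param mask Binary 2D mask, same shape.
#' @param subject,slice,aug Provenance tags.
#' @return Object of class `slice_pair`.
#' @export
slice_pair <- function(image, mask, subject = "unknown", slice = NA_integer_,
                       aug = "orig") {
  stopifnot(identical(dim(image), dim(mask)))
  if (any(mask != 0 & mask != 1)) stop("slice_pair: mask must be binary")
  structure(list(image = image, mask = mask, subject = subject,
                 slice = slice, aug = aug),
            class = "slice_pair")
}

# one randomly parameterized geometric transform, applied identically to the
# image (bilinear) and the mask (re-binarized afterwards)
random_transform <- function() {
  type <- sample(c("flip", "zoom", "shear", "rotate"), 1L)
  par <- switch(type,
                flip = NA_real_,
                zoom = stats::runif(1, 0.9, 1.1),
                shear = stats::runif(1, -10, 10),
                rotate = stats::runif(1, 0, 90))
  list(type = type, par = par)
}

apply_transform <- function(img, tr, is_mask = FALSE) {
  d <- dim(img)
  out <- switch(tr$type,
    flip = img[, rev(seq_len(d[2]))],
    rotate = {
      r <- EBImage::rotate(EBImage::Image(img), tr$par,
                           output.dim = c(d[1], d[2]), bg.col = 0)
      matrix(EBImage::imageData(r), d[1], d[2])
    },
    {
      # zoom / shear: linear map around the image center
      A <- if (tr$type == "zoom") diag(2) * tr$par
           else matrix(c(1, 0, tanpi(tr$par / 180), 1), 2, 2)
      ctr <- (d + 1) / 2
      off <- ctr - A %*% ctr
      m <- rbind(t(A), as.numeric(off))
      r <- EBImage::affine(EBImage::Image(img), m, output.dim = c(d[1], d[2]),
                           bg.col = 0)
      matrix(EBImage::imageData(r), d[1], d[2])
    })
  if (is_mask) out <- (out > 0.5) * 1
  out
}

#' Augment slice pairs
#'
#' Expands the dataset by `factor`: every pair is kept, plus `factor - 1`
#' transformed copies each drawn uniformly from horizontal flip, zoom (0.9 to
#' 1.1), shear (up to 10 degrees) and rotation (0 to 90 degrees). The same
#' geometric transform is applied to image and mask; masks are re-binarized
#' after interpolation.
#'
#' @param pairs List of [slice_pair()] objects.
#' @param factor Expansion factor (>= 1).
#' @param seed Optional seed for exact reproducibility.
#' @return List of `factor * length(pairs)` pairs.
#' @export
augment_pairs <- function(pairs, factor = 3L, seed = NULL) {
  stopifnot(factor >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(pairs) * factor)
  k <- 1L
  for (p in pairs) {
    out[[k]] <- p; k <- k + 1L
    if (factor > 1L) for (j in seq_len(factor - 1L)) {
      tr <- random_transform()
      out[[k]] <- slice_pair(apply_transform(p$image, tr),
                             apply_transform(p$mask, tr, is_mask = TRUE),
                             subject = p$subject, slice = p$slice,
                             aug = sprintf("%s%d", tr$type, j))
      k <- k + 1L
    }
  }
  out
}

#' Shuffle and split pairs into train/validation sets
#'
#' @param pairs List of slice pairs.
#' @param train_frac Training fraction in `(0, 1)`; the training set gets
#'   `round(train_frac * N)` pairs.
#' @param seed Seed for the shuffle.
#' @return Object of class `split_dataset`: list `train`, `validation`,
#'   `seed`, `fractions`.
#' @export
split_pairs <- function(pairs, train_frac = 0.8, seed = 1L) {
  n <- length(pairs)
  if (n < 2L) stop("split_pairs: need at least 2 pairs")
  if (train_frac <= 0 || train_frac >= 1) stop("split_pairs: train_frac in (0,1)")
  set.seed(seed)
  idx <- sample.int(n)
  ntr <- round(train_frac * n)
  structure(list(train = pairs[idx[seq_len(ntr)]],
                 validation = pairs[idx[(ntr + 1L):n]],
                 seed = seed,
                 fractions = c(train = train_frac, validation = 1 - train_frac)),
            class = "split_dataset")
}

#' Full preprocessing of one volume pair
#'
#' Convenience wrapper chaining slice extraction, blank-slice trimming,
#' resizing and normalization into a list of [slice_pair()]s.
#'
#' @param vol Image `stroke_volume`.
#' @param mask Matching mask `stroke_volume`.
#' @param target Output edge length.
#' @param fg_threshold Blank-slice threshold, see [remove_blank_slices()].
#' @return List of slice pairs.
#' @export
preprocess_volume <- function(vol, mask, target = 192L, fg_threshold = 0.02) {
  imgs <- extract_slices(vol)
  msks <- extract_slices(mask)
  tr <- remove_blank_slices(imgs, msks, fg_threshold)
  mapply(function(im, mk, idx) {
    im <- normalize_slice(resize_slice(im, target, "image"))
    mk <- resize_slice((mk > 0.5) * 1, target, "mask")
    slice_pair(im, mk, subject = vol$subject, slice = idx)
  }, tr$slices, tr$masks, tr$indices, SIMPLIFY = FALSE)
}
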