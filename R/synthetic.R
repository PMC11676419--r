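# Seeded generator of brain-like phantom volumes with bright lesion blobs and
# matching binary masks, so the preprocessing pipeline, the training loop and
# the metrics are all testable without any clinical download. Phantoms are
# stacked ellipses with smooth background texture, not anatomy; the defaults
# emulate the scan geometry the pipeline expects (153 slices of 230 x 230
# with blank runs at both ends of the stack).

#' Phantom dataset specification
#'
#' The default geometry mirrors a sub-acute stroke MRI challenge scan: 153
#' axial slices of 230 x 230 voxels at 1 mm spacing, with 46 blank slices at
#' each end of the stack so roughly 61 informative slices survive blank-slice
#' trimming (about 3,900 slices across 64 subjects). Lesions are bright
#' ellipsoidal blobs (+0.4 over a 0.3 background before blurring and noise),
#' chosen so naive intensity thresholding does not solve the segmentation.
#'
#' @param n_subjects Number of subjects.
#' @param n_slices Axial slices per volume.
#' @param slice_size Edge length of each slice in pixels.
#' @param blank_margin Two integers: blank slices at the bottom and top ends.
#' @param lesion_count Integer range (min, max) of lesions per subject.
#' @param lesion_radius In-plane lesion radius range in pixels.
#' @param intensity_boost Lesion brightness added over the background.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param background Mean background intensity inside the brain ellipse.
#' @param seed Base seed; fixed seed implies bit-identical output.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_subjects = 64L, n_slices = 153L, slice_size = 230L,
                         blank_margin = c(46L, 46L), lesion_count = c(1L, 3L),
                         lesion_radius = c(4L, 18L), intensity_boost = 0.4,
                         noise_sd = 0.05, background = 0.3, seed = 1L) {
  stopifnot(n_subjects >= 1, n_slices >= 1, slice_size >= 16,
            length(blank_margin) == 2L, all(blank_margin >= 0),
            length(lesion_count) == 2L, lesion_count[1] >= 1,
            length(lesion_radius) == 2L, lesion_radius[1] >= 1)
  if (sum(blank_margin) >= n_slices)
    stop("phantom_spec: blank margins leave no informative slices")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_slices = as.integer(n_slices),
                 slice_size = as.integer(slice_size),
                 blank_margin = as.integer(blank_margin),
                 lesion_count = as.integer(lesion_count),
                 lesion_radius = as.integer(lesion_radius),
                 intensity_boost = intensity_boost,
                 noise_sd = noise_sd,
                 background = background,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth low-frequency texture field in [-amp, amp]
smooth_texture <- function(n, amp = 0.05) {
  coarse <- matrix(stats::runif((n %/% 8 + 2)^2, -1, 1), n %/% 8 + 2)
  up <- EBImage::resize(EBImage::Image(coarse), w = n, h = n, filter = "bilinear")
  amp * matrix(EBImage::imageData(up), n, n)
}

#' Generate one phantom volume and its lesion mask
#'
#' @param spec A [phantom_spec()].
#' @param subject Subject index (drives the per-subject RNG stream).
#' @return List with `volume` and `mask`, both `stroke_volume` objects; the
#'   mask is 1 exactly where lesion membership was drawn, always inside the
#'   brain ellipse.
#' @export
make_phantom <- function(spec, subject = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$slice_size
  ns <- spec$n_slices
  ax_a <- 0.42 * n; ax_b <- 0.36 * n      # brain ellipse semi-axes
  if (spec$lesion_radius[2] >= ax_b)
    stop("make_phantom: lesion radius exceeds the brain region")
  set.seed((spec$seed * 2048L + subject * 31L) %% .Machine$integer.max)

  ctr <- (n + 1) / 2
  xx <- matrix(rep(seq_len(n), each = n), n)   # column index
  yy <- matrix(rep(seq_len(n), n), n)          # row index
  brain <- ((yy - ctr) / ax_a)^2 + ((xx - ctr) / ax_b)^2 <= 1

  lo <- spec$blank_margin[1] + 1L
  hi <- ns - spec$blank_margin[2]
  vol <- array(0, dim = c(ns, n, n))
  msk <- array(0, dim = c(ns, n, n))

  n_les <- sample(spec$lesion_count[1]:spec$lesion_count[2], 1L)
  lesions <- lapply(seq_len(n_les), function(i) {
    r <- stats::runif(1, spec$lesion_radius[1], spec$lesion_radius[2])
    rz <- max(1, r * stats::runif(1, 0.3, 0.6))
    # center well inside the brain ellipse and the informative slice range
    repeat {
      cy <- stats::runif(1, ctr - 0.7 * ax_a, ctr + 0.7 * ax_a)
      cx <- stats::runif(1, ctr - 0.7 * ax_b, ctr + 0.7 * ax_b)
      if (((cy - ctr) / ax_a)^2 + ((cx - ctr) / ax_b)^2 <= 0.49) break
    }
    cz <- if (hi - rz > lo + rz) stats::runif(1, lo + rz, hi - rz)
          else (lo + hi) / 2
    list(cy = cy, cx = cx, cz = cz, r = r, rz = rz)
  })

  for (k in lo:hi) {
    img <- spec$background + smooth_texture(n)
    img[!brain] <- 0
    les_k <- matrix(0, n, n)
    for (L in lesions) {
      dz2 <- ((k - L$cz) / L$rz)^2
      if (dz2 <= 1) {
        inplane <- ((yy - L$cy)^2 + (xx - L$cx)^2) / L$r^2
        les_k[inplane + dz2 <= 1] <- 1
      }
    }
    les_k[!brain] <- 0
    if (any(les_k > 0)) {
      boost <- EBImage::gblur(EBImage::Image(les_k * spec$intensity_boost),
                              sigma = 2)
      img <- img + matrix(EBImage::imageData(boost), n, n)
    }
    img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
    img[img < 0] <- 0
    img[!brain] <- 0
    vol[k, , ] <- img
    msk[k, , ] <- les_k
  }
  subj <- sprintf("sub-%03d", subject)
  list(volume = new_stroke_volume(vol, subject = subj, modality = "DWI"),
       mask = new_stroke_volume(msk, subject = subj, modality = "mask"))
}

#' Write a phantom dataset to disk
#'
#' Generates `spec$n_subjects` volume/mask NIfTI pairs plus a `manifest.csv`
#' (one row per subject: subject id, image path, mask path, slice count).
#'
#' @param spec A [phantom_spec()].
#' @param dir Writable output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
make_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    ph <- make_phantom(spec, s)
    fimg <- file.path(dir, sprintf("sub-%03d_image.nii.gz", s))
    fmsk <- file.path(dir, sprintf("sub-%03d_mask.nii.gz", s))
    save_volume(ph$volume, fimg)
    save_volume(ph$mask, fmsk)
    rows[[s]] <- data.frame(subject = ph$volume$subject, image = fimg,
                            mask = fmsk, n_slices = spec$n_slices,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
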