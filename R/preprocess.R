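ALLOWED_LABELS <- c(0L, 1L, 2L, 4L)

#' Load a NIfTI volume/label pair
#'
#' Reads a scan and its integer label volume, checks that the two grids are
#' aligned and that label values are restricted to the BraTS code set
#' \{0, 1, 2, 4\} (1 = necrotic/non-enhancing core, 2 = edema, 4 = enhancing
#' tumor). An unknown label value is a hard error naming the value, distinct
#' from a missing-file error.
#'
#' @param image_path path to the scan (.nii / .nii.gz).
#' @param label_path path to the label volume.
#' @return list with `volume` (numeric array), `label` (integer array), `id`.
#' @export
load_volume <- function(image_path, label_path) {
  if (!file.exists(image_path))
    stop("image file not found: ", image_path)
  if (!file.exists(label_path))
    stop("label file not found: ", label_path)
  strip <- function(x) {
    a <- as.array(x)
    attributes(a) <- list(dim = dim(a))
    a
  }
  vol <- strip(RNifti::readNifti(image_path))
  lab <- strip(RNifti::readNifti(label_path))
  if (!identical(dim(vol), dim(lab)))
    stop("shape mismatch between image ", paste(dim(vol), collapse = "x"),
         " and label ", paste(dim(lab), collapse = "x"))
  bad <- setdiff(unique(as.vector(lab)), ALLOWED_LABELS)
  if (length(bad) > 0)
    stop("unknown label value(s): ", paste(bad, collapse = ", "),
         " (allowed: 0, 1, 2, 4)")
  storage.mode(lab) <- "integer"
  list(volume = vol, label = lab,
       id = sub("\\.nii(\\.gz)?$", "", basename(image_path)))
}

#' Clip the brightest intensities of a volume
#'
#' Replaces every value above the `1 - fraction` quantile by that quantile,
#' damping the sharp high end of the intensity distribution (off-resonance
#' bright spots). The default removes the top 0.5%. The inverse-CDF quantile
#' (an observed voxel value) is used, which makes the operation exactly
#' idempotent; it is the identity for `fraction = 0` or a constant volume.
#'
#' @param volume numeric array.
#' @param fraction upper-tail fraction in `[0, 0.5)`.
#' @return clipped array of the same shape.
#' @export
clip_high_intensities <- function(volume, fraction = 0.005) {
  stopifnot(fraction >= 0, fraction < 0.5)
  if (fraction == 0) return(volume)
  q <- quantile(volume, probs = 1 - fraction, names = FALSE, type = 1)
  pmin(volume, q)
}

#' Resample a volume to a fixed slice count
#'
#' Linear interpolation of intensities along the slice axis; nearest-neighbour
#' for labels so the label value set is preserved. In-plane resolution is
#' unchanged. With `n_slices` equal to the input slice count the output is
#' voxel-identical.
#'
#' @param volume `H x W x S` numeric array.
#' @param label matching integer label array.
#' @param n_slices target slice count (default 21, the standardized stack
#'   depth used throughout the package; see the methods vignette).
#' @return list with resampled `volume` and `label`.
#' @export
resample_to_slices <- function(volume, label, n_slices = 21L) {
  stopifnot(n_slices >= 1, identical(dim(volume), dim(label)))
  s <- dim(volume)[3]
  if (s == n_slices) return(list(volume = volume, label = label))
  if (s == 1L) {
    idx <- rep(1L, n_slices)
    return(list(volume = volume[, , idx, drop = FALSE],
                label = label[, , idx, drop = FALSE]))
  }
  t <- if (n_slices == 1L) (s + 1) / 2 else seq(1, s, length.out = n_slices)
  lo <- pmin(floor(t), s - 1); w <- t - lo
  h <- dim(volume)[1]; wd <- dim(volume)[2]
  out_v <- array(0, dim = c(h, wd, n_slices))
  for (k in seq_len(n_slices))
    out_v[, , k] <- (1 - w[k]) * volume[, , lo[k]] + w[k] * volume[, , lo[k] + 1]
  nn <- pmin(pmax(floor(t + 0.5), 1), s)
  out_l <- label[, , nn, drop = FALSE]
  list(volume = out_v, label = out_l)
}

#' Crop the in-plane region of interest around the labelled foreground
#'
#' Computes the tight in-plane bounding box of nonzero label voxels over all
#' slices, expands it by `margin` voxels and clamps to the grid. All slices
#' are kept; all nonzero label voxels are retained.
#'
#' @param volume `H x W x S` numeric array.
#' @param label matching label array with at least one nonzero voxel.
#' @param margin margin in voxels (default 8).
#' @return list with cropped `volume` and `label`.
#' @export
crop_roi <- function(volume, label, margin = 8L) {
  stopifnot(identical(dim(volume), dim(label)), margin >= 0)
  fg <- which(label != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("cannot crop ROI: label volume has no foreground")
  r <- c(max(1L, min(fg[, 1]) - margin), min(dim(label)[1], max(fg[, 1]) + margin))
  cc <- c(max(1L, min(fg[, 2]) - margin), min(dim(label)[2], max(fg[, 2]) + margin))
  list(volume = volume[r[1]:r[2], cc[1]:cc[2], , drop = FALSE],
       label = label[r[1]:r[2], cc[1]:cc[2], , drop = FALSE])
}

#' Merge all tumor sub-region labels into one binary foreground class
#'
#' Maps 0 to 0 and 1, 2, 4 to 1: the different tumor levels are clustered into
#' a single whole-tumor class for one-prototype segmentation.
#'
#' @param label integer array with values in \{0, 1, 2, 4\}.
#' @return integer array of the same shape with values in \{0, 1\}.
#' @export
binarize_labels <- function(label) {
  out <- array(as.integer(label != 0), dim = dim(label))
  out
}

#' Standardize a cropped volume into the model-facing slice stack
#'
#' Resizes every slice to `side x side` (bilinear for images, nearest for
#' masks), min-max normalizes the image volume to `[0, 1]` (a constant volume
#' maps to all zeros), and replicates the single channel three times to fit a
#' 3-channel encoder input. Normalization is per volume, not per slice:
#' whole-scan inference scores every slice against one support prototype, so
#' the relative brightness of slices must be preserved — per-slice rescaling
#' would stretch tumor-free slices to the full range and make healthy tissue
#' mimic tumor intensity.
#'
#' @param volume `H x W x S` numeric array.
#' @param mask matching binary mask array.
#' @param side output side length (default 256).
#' @param id case identifier carried along.
#' @return a `slice_stack`: list with `images` (`S x 3 x side x side`),
#'   `masks` (`S x side x side`, values in \{0,1\}) and `id`.
#' @export
standardize_stack <- function(volume, mask, side = 256L, id = "case") {
  stopifnot(identical(dim(volume), dim(mask)))
  s <- dim(volume)[3]
  rng <- range(volume)
  volume <- if (rng[2] > rng[1]) (volume - rng[1]) / (rng[2] - rng[1])
            else volume * 0
  images <- array(0, dim = c(s, 3L, side, side))
  masks <- array(0L, dim = c(s, side, side))
  for (k in seq_len(s)) {
    img <- pmin(pmax(resize_bilinear(volume[, , k], c(side, side)), 0), 1)
    for (ch in 1:3) images[k, ch, , ] <- img
    masks[k, , ] <- as.integer(resize_nearest(mask[, , k] != 0, c(side, side)))
  }
  structure(list(images = images, masks = masks, id = id), class = "slice_stack")
}

#' Default augmentation bounds
#'
#' @param rotation max |rotation| in degrees.
#' @param translate max |translation| in pixels.
#' @param shear max |shear| in degrees.
#' @param prob per-slice probability of applying a transform.
#' @return list of bounds.
#' @export
augment_config <- function(rotation = 15, translate = 10, shear = 10, prob = 0.5) {
  stopifnot(rotation >= 0, translate >= 0, shear >= 0, prob >= 0, prob <= 1)
  list(rotation = rotation, translate = translate, shear = shear, prob = prob)
}

#' Random affine augmentation of a slice stack
#'
#' With probability `prob` per slice, applies one random affine transform
#' (rotation, translation, shear within the configured bounds) identically to
#' the image channels (bilinear) and the mask (nearest, re-binarized). Slices
#' are replaced in place — the dataset size is unchanged. Consumes the current
#' RNG stream; seed beforehand for reproducibility. Zero-amplitude bounds give
#' an exact identity.
#'
#' @param images `N x 3 x H x W` array.
#' @param masks `N x H x W` binary array.
#' @param config an [augment_config()].
#' @return list with augmented `images` and `masks`.
#' @export
augment <- function(images, masks, config = augment_config()) {
  stopifnot(length(dim(images)) == 4, length(dim(masks)) == 3,
            dim(images)[1] == dim(masks)[1],
            all(dim(images)[3:4] == dim(masks)[2:3]))
  n <- dim(images)[1]
  for (k in seq_len(n)) {
    if (runif(1) >= config$prob) next
    rot <- runif(1, -config$rotation, config$rotation)
    tr <- runif(2, -config$translate, config$translate)
    shr <- runif(1, -config$shear, config$shear)
    for (ch in seq_len(dim(images)[2]))
      images[k, ch, , ] <- warp_affine(images[k, ch, , ], rot, shr, tr, "bilinear")
    m <- warp_affine(masks[k, , ], rot, shr, tr, "nearest")
    masks[k, , ] <- as.integer(m != 0)
  }
  list(images = images, masks = masks)
}

#' Full preprocessing chain for one case
#'
#' Applies, in order: intensity clipping, slice resampling, ROI cropping,
#' label binarization, and stack standardization (resize, normalize,
#' channel replication).
#'
#' @param volume numeric array, `H x W x S`.
#' @param label matching label array.
#' @param n_slices target slice count (default 21).
#' @param clip_fraction upper-tail clip fraction (default 0.005).
#' @param margin ROI margin in voxels (default 8).
#' @param side output side (default 256).
#' @param id case identifier.
#' @return a `slice_stack`.
#' @export
preprocess_case <- function(volume, label, n_slices = 21L, clip_fraction = 0.005,
                            margin = 8L, side = 256L, id = "case") {
  vol <- clip_high_intensities(volume, clip_fraction)
  rs <- resample_to_slices(vol, label, n_slices)
  cr <- crop_roi(rs$volume, rs$label, margin)
  mask <- binarize_labels(cr$label)
  standardize_stack(cr$volume, mask, side = side, id = id)
}

#' Load and preprocess every case listed in a dataset manifest
#'
#' @param dir directory containing NIfTI pairs and `manifest.json` as written
#'   by [generate_dataset()].
#' @param ... passed to [preprocess_case()].
#' @return list of `slice_stack` objects.
#' @export
load_dataset <- function(dir, ...) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(manifest$cases, function(cs) {
    pair <- load_volume(file.path(dir, cs$image), file.path(dir, cs$label))
    preprocess_case(pair$volume, pair$label, id = cs$id, ...)
  })
}
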