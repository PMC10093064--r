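#' Configuration for the synthetic MRI-like volume generator
#'
#' The generator emulates the gross statistics of T2-weighted brain scans with
#' an expert-labelled tumor: ~150 axial slices, an ellipsoidal brain region on
#' a dark surround, and a small bright, heterogeneous tumor whose size,
#' location and intensity vary per case. Tumor sub-regions are nested
#' concentrically and labelled with the BraTS code set (1 = necrotic core /
#' non-enhancing, 2 = edema, 4 = enhancing), label 4 innermost and 2 outermost,
#' so that downstream class merging is exercised.
#'
#' @param n_slices number of axial slices (default 150, the dataset-typical
#'   slice count the generator emulates).
#' @param grid in-plane `c(height, width)` in voxels; each side must be >= 32.
#' @param tumor_radius_range interval of tumor semi-axis lengths, as a fraction
#'   of the corresponding grid dimension; must lie inside (0, 0.5).
#' @param tumor_intensity `c(mean, sd)` of tumor tissue intensity (a.u.).
#' @param background_intensity `c(mean, sd)` of brain tissue intensity (a.u.).
#' @param noise_sd standard deviation of additive voxel noise (a.u.).
#' @param n_label_levels number of distinct tumor label levels in 1..3
#'   (1 -> \{4\}, 2 -> \{2,4\}, 3 -> \{1,2,4\}).
#' @param seed default seed used by [generate_dataset()].
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_slices = 150L,
                         grid = c(96L, 96L),
                         tumor_radius_range = c(0.08, 0.18),
                         tumor_intensity = c(mean = 300, sd = 30),
                         background_intensity = c(mean = 100, sd = 20),
                         noise_sd = 10,
                         n_label_levels = 3L,
                         seed = 1L) {
  stopifnot(n_slices >= 3, length(grid) == 2)
  if (any(grid < 32)) stop("degenerate grid: each side must be >= 32 voxels")
  stopifnot(length(tumor_radius_range) == 2,
            tumor_radius_range[1] <= tumor_radius_range[2])
  if (tumor_radius_range[1] <= 0 || tumor_radius_range[2] >= 0.5)
    stop("tumor_radius_range must lie within (0, 0.5)")
  stopifnot(tumor_intensity[2] >= 0, background_intensity[2] >= 0, noise_sd >= 0,
            n_label_levels %in% 1:3)
  structure(list(
    n_slices = as.integer(n_slices), grid = as.integer(grid),
    tumor_radius_range = tumor_radius_range,
    tumor_intensity = tumor_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd, n_label_levels = as.integer(n_label_levels),
    seed = as.integer(seed)), class = "synth_config")
}

# squared normalized ellipsoid distance field on the (H, W, S) grid
ellipsoid_field <- function(h, w, s, centre, radii) {
  a <- ((seq_len(h) - centre[1]) / radii[1])^2
  b <- ((seq_len(w) - centre[2]) / radii[2])^2
  cc <- ((seq_len(s) - centre[3]) / radii[3])^2
  outer(outer(a, b, `+`), cc, `+`)
}

#' Generate one synthetic volume/label pair
#'
#' Deterministic for a fixed `(config, seed)` pair. The tumor is an
#' axis-aligned ellipsoid with jittered centre and semi-axes, intersecting at
#' least three slices; its intensity rises towards the core. Labels are nested
#' shells drawn from \{1, 2, 4\} according to `n_label_levels`. Intensities are
#' clipped at 0 and intended for 32-bit float storage.
#'
#' @param config a [synth_config()].
#' @param seed integer seed for this case.
#' @return list with `volume` (`H x W x S` numeric array), `label`
#'   (`H x W x S` integer array with values in \{0,1,2,4\}), `id`, `seed`.
#' @export
generate_case <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(seed, {
    h <- config$grid[1]; w <- config$grid[2]; s <- config$n_slices
    # brain: centred ellipsoid of tissue on a dark noisy surround
    brain <- ellipsoid_field(h, w, s,
                             centre = c((h + 1) / 2, (w + 1) / 2, (s + 1) / 2),
                             radii = c(0.42 * h, 0.42 * w, 0.46 * s)) <= 1
    vol <- array(abs(rnorm(h * w * s, 0, config$noise_sd / 2)), dim = c(h, w, s))
    # smooth per-case intensity gradient across the brain (field inhomogeneity)
    gdir <- rnorm(3); gdir <- gdir / sqrt(sum(gdir^2))
    grad <- ellipsoid_field(h, w, s, centre = c(1, 1, 1),
                            radii = c(h, w, s) / abs(gdir + 2))  # mild, smooth
    grad <- (grad - mean(grad)) / max(abs(grad - mean(grad)))
    bg <- config$background_intensity
    vol[brain] <- bg["mean"] + bg["sd"] * grad[brain] +
      rnorm(sum(brain), 0, config$noise_sd)
    # tumor: jittered ellipsoid inside the brain
    fr <- config$tumor_radius_range
    centre <- c(runif(1, 0.38 * h, 0.62 * h),
                runif(1, 0.38 * w, 0.62 * w),
                runif(1, 0.40 * s, 0.60 * s))
    radii <- c(runif(1, fr[1], fr[2]) * h,
               runif(1, fr[1], fr[2]) * w,
               max(2, runif(1, fr[1], fr[2]) * s))
    d <- ellipsoid_field(h, w, s, centre, radii)
    tum <- d <= 1
    ti <- config$tumor_intensity
    vol[tum] <- ti["mean"] + ti["sd"] * (1 - d[tum]) +
      rnorm(sum(tum), 0, config$noise_sd)
    lab <- array(0L, dim = c(h, w, s))
    levels <- switch(as.character(config$n_label_levels),
                     "1" = 4L, "2" = c(2L, 4L), "3" = c(2L, 1L, 4L))
    # nested shells: outermost first so inner assignments overwrite
    scales <- rev(seq_len(length(levels))) / length(levels)  # 1, 2/3, 1/3
    for (i in seq_along(levels)) lab[d <= scales[i]^2] <- levels[i]
    list(volume = pmax(vol, 0), label = lab,
         id = sprintf("case_%09d", seed), seed = as.integer(seed))
  })
}

#' Generate and write a synthetic dataset
#'
#' Writes `n_cases` NIfTI volume/label pairs plus a JSON manifest listing
#' paths and per-case seeds (distinct, derived deterministically from `seed`).
#'
#' @param n_cases number of cases (>= 1).
#' @param config a [synth_config()].
#' @param out_dir output directory.
#' @param seed master seed.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest, invisibly.
#' @export
generate_dataset <- function(n_cases, config = synth_config(), out_dir,
                             seed = config$seed, overwrite = FALSE) {
  if (n_cases < 1) stop("n_cases must be >= 1")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is non-empty; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  case_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n_cases))
  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cs <- generate_case(config, seed = case_seeds[i])
    img_path <- file.path(out_dir, sprintf("case%03d_img.nii.gz", i))
    lab_path <- file.path(out_dir, sprintf("case%03d_lab.nii.gz", i))
    RNifti::writeNifti(cs$volume, img_path, datatype = "float")
    RNifti::writeNifti(cs$label, lab_path, datatype = "uint8")
    cases[[i]] <- list(id = cs$id, image = basename(img_path),
                       label = basename(lab_path), seed = case_seeds[i])
  }
  manifest <- list(n_cases = n_cases, seed = as.integer(seed), cases = cases)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
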