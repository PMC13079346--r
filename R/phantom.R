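# Synthetic multi-sequence brain phantom. Concentric ellipsoids provide
# background, a skull ring (non-brain), cortex, white matter and ventricles,
# plus small off-center blobs for small-structure classes; each MRI "sequence"
# renders the same tissue layout through its own contrast lookup table (LUT),
# so ground-truth masks and labels are exact and shared across sequences.

default_luts <- function(n_tissues) {
  # rows: sequences, columns: tissue classes (0 = background first).
  # distinct orderings across sequences keep sequence identity learnable.
  # orderings and pairwise ratios chosen to stay well separated after
  # per-slice min-max normalization (the slice-level signal is relative, not
  # absolute, intensity)
  base <- list(
    T1    = c(0.00, 0.95, 0.40, 0.75, 0.10, 0.55, 0.30),
    T2    = c(0.00, 0.15, 0.55, 0.30, 0.95, 0.75, 0.45),
    FLAIR = c(0.00, 0.55, 0.90, 0.65, 0.05, 0.25, 0.80),
    PD    = c(0.00, 0.30, 0.75, 0.95, 0.55, 0.40, 0.85)
  )
  lapply(base, function(v) v[seq_len(n_tissues)])
}

#' Specification of a synthetic brain phantom
#'
#' @param grid_size Voxels per axis (cubic grid), at least 16.
#' @param n_tissues Number of anatomical classes including background
#'   (default 6: background, skull ring, cortex, white matter, ventricles,
#'   small blobs). The skull ring is rendered in the image but is *not* brain:
#'   it is excluded from the brain mask and coded 0 in the label map.
#' @param sequences Named list of per-tissue mean-intensity lookup tables in
#'   `[0, 1]`, one numeric vector of length `n_tissues` per sequence. Defaults
#'   to four contrasts with distinct intensity orderings.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param coverage_profile Character subset of `c("full", "partial", "empty")`;
#'   which brain-coverage categories must occur among axial slices. Apex/base
#'   slices give partial coverage naturally; "empty" forces brain-free slices
#'   at the volume ends.
#' @param voxel_size_mm Length-3 positive voxel sizes in mm.
#' @param seed RNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_size = 64, n_tissues = 6,
                         sequences = NULL,
                         noise_sd = 0.02,
                         coverage_profile = c("full", "partial", "empty"),
                         voxel_size_mm = c(1, 1, 1),
                         seed = 1L) {
  stop_if(!is_count(grid_size, 16), "`grid_size` must be an integer >= 16.")
  stop_if(!is_count(n_tissues, 2), "`n_tissues` must be an integer >= 2.",
          class = "maefunet_invalid_spec")
  stop_if(n_tissues > 7, "at most 7 tissue classes are supported.")
  stop_if(!is.numeric(noise_sd) || noise_sd < 0, "`noise_sd` must be >= 0.")
  stop_if(!all(voxel_size_mm > 0) || length(voxel_size_mm) != 3,
          "`voxel_size_mm` must be 3 positive values.")
  sequences <- sequences %||% default_luts(n_tissues)
  stop_if(is.null(names(sequences)) || any(!nzchar(names(sequences))),
          "`sequences` must be a named list of LUTs.")
  for (lut in sequences) {
    stop_if(length(lut) != n_tissues || any(lut < 0 | lut > 1),
            "each LUT must have one value in [0,1] per tissue class.")
  }
  coverage_profile <- match.arg(coverage_profile, several.ok = TRUE)
  structure(list(grid_size = as.integer(grid_size), n_tissues = as.integer(n_tissues),
                 sequences = sequences, noise_sd = noise_sd,
                 coverage_profile = coverage_profile,
                 voxel_size_mm = as.numeric(voxel_size_mm), seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_mask <- function(n, center, radii) {
  ax <- seq_len(n)
  dx <- (ax - center[1]) / radii[1]
  dy <- (ax - center[2]) / radii[2]
  dz <- (ax - center[3]) / radii[3]
  d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  d2 <= 1
}

phantom_labels <- function(spec, rng_offsets) {
  n <- spec$grid_size
  c0 <- rep((n + 1) / 2, 3) + rng_offsets$center
  labels <- array(0L, dim = c(n, n, n))
  skull <- array(FALSE, dim = c(n, n, n))
  # concentric ellipsoids, outermost first; axis 3 (axial) shorter so apex/base
  # slices have low or zero brain coverage
  r_skull  <- c(0.44, 0.40, 0.36) * n
  r_brain  <- c(0.38, 0.34, 0.30) * n
  r_wm     <- c(0.27, 0.24, 0.21) * n
  r_vent   <- c(0.10, 0.08, 0.07) * n
  skull[ellipsoid_mask(n, c0, r_skull)] <- TRUE
  cortex <- ellipsoid_mask(n, c0, r_brain)
  labels[cortex] <- 2L                      # cortex
  if (spec$n_tissues >= 4) labels[ellipsoid_mask(n, c0, r_wm)] <- 3L    # white matter
  if (spec$n_tissues >= 5) labels[ellipsoid_mask(n, c0, r_vent)] <- 4L  # ventricles
  if (spec$n_tissues >= 6) {
    # small off-center blobs (hippocampus/amygdala-like small structures)
    for (off in rng_offsets$blobs) {
      labels[ellipsoid_mask(n, c0 + off, rep(0.045 * n, 3))] <- 5L
    }
  }
  if (spec$n_tissues >= 7) {
    labels[ellipsoid_mask(n, c0 + rng_offsets$blob7, rep(0.06 * n, 3))] <- 6L
  }
  skull <- skull & labels == 0L            # ring outside the brain
  labels[skull] <- 1L                       # skull class (non-brain)
  brain <- labels >= 2L
  if ("empty" %in% spec$coverage_profile) {
    # crop the head out of the last axial slices entirely (cropped FOV)
    kcut <- max(1L, round(0.06 * n))
    idx <- (n - kcut + 1L):n
    labels[, , idx] <- 0L
    brain[, , idx] <- FALSE
    skull[, , idx] <- FALSE
  }
  list(labels = labels, brain = brain, skull = skull)
}

#' Generate a multi-sequence synthetic brain phantom
#'
#' Renders one volume per sequence from a shared tissue layout; all sequences
#' share identical `brain_mask` and `labels` and differ only in intensities.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return Named list of `phantom_volume` objects (one per sequence), each with
#'   `image` (3D array in `[0,1]`), `brain_mask` (logical 3D), `labels`
#'   (integer 3D, 0 = background/non-brain, skull coded separately in
#'   `skull_mask`), `voxel_size_mm`, and `sequence`.
#' @export
generate_phantom <- function(spec) {
  stop_if(!inherits(spec, "phantom_spec"), "`spec` must come from phantom_spec().",
          class = "maefunet_invalid_spec")
  n <- spec$grid_size
  set.seed(spec$seed)
  rng_offsets <- list(
    center = round(runif(3, -0.02, 0.02) * n),
    blobs = list(round(c(0.16, 0.10, -0.04) * n), round(c(-0.17, -0.08, 0.02) * n)),
    blob7 = round(c(0.02, -0.18, 0.05) * n)
  )
  geo <- phantom_labels(spec, rng_offsets)
  render_labels <- geo$labels
  render_labels[geo$skull] <- 1L
  out <- list()
  for (seq_name in names(spec$sequences)) {
    lut <- spec$sequences[[seq_name]]
    img <- array(lut[render_labels + 1L], dim = dim(render_labels))
    if (spec$noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    lbl <- geo$labels
    lbl[lbl == 1L] <- 0L                   # skull is non-brain: background in labels
    lbl[lbl >= 2L] <- lbl[lbl >= 2L] - 1L  # brain classes contiguous from 1
    vol <- structure(list(image = img, brain_mask = geo$brain, labels = lbl,
                          skull_mask = geo$skull,
                          voxel_size_mm = spec$voxel_size_mm,
                          sequence = seq_name),
                     class = "phantom_volume")
    out[[seq_name]] <- vol
  }
  out
}

#' Brain coverage of a 2D mask slice
#'
#' The coverage fraction alpha is the share of pixels inside the binary brain
#' mask; it drives the per-sample weight of the pretraining loss.
#'
#' @param mask_slice 2D binary array (logical or 0/1).
#' @return Fraction in `[0, 1]`.
#' @export
brain_coverage <- function(mask_slice) {
  stop_if(length(mask_slice) == 0L, "empty mask.")
  v <- as.numeric(mask_slice)
  stop_if(anyNA(v) || any(v != 0 & v != 1), "mask must be binary.")
  sum(v) / length(v)
}

#' Write a phantom to NIfTI files with a JSON manifest
#'
#' One image volume per sequence plus shared brain-mask and label volumes,
#' with voxel sizes recorded in the NIfTI headers, and a `manifest.json`
#' mapping sequences to files.
#'
#' @param volumes Output of [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @param spec The generating [phantom_spec()] (hashed into the manifest).
#' @return Invisibly, the manifest list.
#' @export
write_phantom <- function(volumes, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- volumes[[1]]$voxel_size_mm
  files <- list()
  for (seq_name in names(volumes)) {
    f <- file.path(dir, paste0(seq_name, ".nii.gz"))
    write_nifti_volume(volumes[[seq_name]]$image, f, vox)
    files[[seq_name]] <- basename(f)
  }
  write_nifti_volume(volumes[[1]]$brain_mask * 1L, file.path(dir, "brain_mask.nii.gz"), vox)
  write_nifti_volume(volumes[[1]]$labels, file.path(dir, "labels.nii.gz"), vox)
  manifest <- list(sequences = files, brain_mask = "brain_mask.nii.gz",
                   labels = "labels.nii.gz", voxel_size_mm = vox,
                   seed = if (!is.null(spec)) spec$seed else NA,
                   spec_hash = if (!is.null(spec)) rlang::hash(spec) else NA)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return List with `data` (array) and `voxel_size_mm`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = unclass(img)[,,, drop = TRUE], voxel_size_mm = RNifti::pixdim(img))
}

#' Write a NIfTI volume
#'
#' @param data 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Length-3 voxel sizes stored in the header.
#' @return Invisibly, `path`.
#' @export
write_nifti_volume <- function(data, path, voxel_size_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
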