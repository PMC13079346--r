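# Few-shot dataset construction: sparse stride sampling along an acquisition
# axis, tri-axial remapping of volumes to 2D slices with empty-mask filtering,
# and seeded slice-level / volume-level train-test splits with volume-level
# leakage guards. Manifests are tibbles (one row per slice).

#' Sparse stride sampling of slice indices
#'
#' Keeps slices at 1-based multiples of the stride `k` (returned as 0-based
#' indices `k-1, 2k-1, ...`), so exactly `floor(n / k)` slices are retained.
#' On a volume standardized to 224 slices this yields 56, 44, 37, 32, 28, 24,
#' 22 training slices for strides 4 through 10.
#'
#' @param n_slices_on_axis Number of slices along the sampling axis.
#' @param k Stride (>= 1).
#' @return Integer vector of 0-based slice indices (empty, with a warning, when
#'   `k > n`).
#' @export
stride_sample <- function(n_slices_on_axis, k) {
  stop_if(!is_count(n_slices_on_axis, 1), "`n_slices_on_axis` must be a positive integer.")
  stop_if(!is_count(k, 1), "`k` must be a positive integer.")
  if (k > n_slices_on_axis) {
    rlang::warn("stride exceeds the number of slices: empty selection.")
    return(integer(0))
  }
  seq.int(k, n_slices_on_axis, by = k) - 1L
}

extract_slice <- function(volume, axis, index0) {
  i <- index0 + 1L
  pick <- function(a) {
    if (is.null(a)) return(NULL)
    s <- switch(axis, a[i, , ], a[, i, ], a[, , i])
    matrix(s, dim(a)[setdiff(1:3, axis)][1])
  }
  list(image = pick(volume$image), brain_mask = pick(volume$brain_mask),
       labels = pick(volume$labels))
}

axis_id <- c(sagittal = 1L, coronal = 2L, axial = 3L)

#' Remap a 3D volume to 2D slices along one or more axes
#'
#' Emits every slice along each requested anatomical axis (sagittal = axis 1,
#' coronal = 2, axial = 3), dropping slices whose label-foreground pixel count
#' is below `min_foreground` ("no meaningful mask"). Provenance (volume id,
#' axis, 0-based index) is recorded per slice.
#'
#' @param volume Volume list with `image` and (if filtering) `labels`;
#'   `brain_mask` is carried along when present. Expected to be isotropically
#'   resampled first (see [resample_isotropic()]).
#' @param axes Character subset of `c("sagittal", "coronal", "axial")`.
#' @param min_foreground Minimum number of nonzero label pixels to keep a
#'   slice (default 1). Use 0 to keep all slices.
#' @param volume_id Identifier recorded in provenance.
#' @param indices Optional named list (per axis) of 0-based indices to emit
#'   (e.g. from [stride_sample()]); default all slices.
#' @return List of `slice_sample` objects (images are raw, not yet normalized).
#' @export
remap_volume_to_slices <- function(volume, axes = c("sagittal", "coronal", "axial"),
                                   min_foreground = 1, volume_id = "vol",
                                   indices = NULL) {
  axes <- match.arg(axes, several.ok = TRUE)
  stop_if(min_foreground > 0 && is.null(volume$labels),
          "`labels` required when min_foreground > 0.")
  out <- list()
  for (ax_name in axes) {
    ax <- axis_id[[ax_name]]
    n_ax <- dim(volume$image)[ax]
    idx <- indices[[ax_name]] %||% (seq_len(n_ax) - 1L)
    for (i0 in idx) {
      sl <- extract_slice(volume, ax, i0)
      if (min_foreground > 0 && sum(sl$labels != 0) < min_foreground) next
      img <- clamp_normalize(sl$image)
      out[[length(out) + 1L]] <- slice_sample_new(
        img, brain_mask = sl$brain_mask, labels = sl$labels,
        provenance = list(volume = volume_id, axis = ax_name, index = i0))
    }
  }
  out
}

slice_manifest <- function(samples, sequence = NA_character_, split = NA_character_) {
  tibble::tibble(
    volume = purrr::map_chr(samples, ~ as.character(.x$provenance$volume %||% NA)),
    axis = purrr::map_chr(samples, ~ as.character(.x$provenance$axis %||% NA)),
    index = purrr::map_int(samples, ~ as.integer(.x$provenance$index %||% NA)),
    sequence = sequence,
    split = split,
    alpha = purrr::map_dbl(samples, ~ as.numeric(.x$alpha %||% NA))
  )
}

#' Slice-level few-shot split for sequence classification
#'
#' For each sequence, training slices are drawn without replacement from the
#' training volumes and test slices from held-out volumes; no volume
#' contributes to both splits. Sampling is seeded and reproducible.
#'
#' @param volumes_by_sequence Named list (one entry per sequence) of lists of
#'   volumes; each volume needs `image` (and optionally `brain_mask`).
#' @param n_slices_per_sequence Training slices per sequence.
#' @param seed RNG seed.
#' @param axis Slicing axis (default axial).
#' @param n_test_per_sequence Test slices per sequence (default 2 x train).
#' @param min_alpha Minimum brain coverage for a slice to enter the pool
#'   (default 0.25, the full-coverage category): after per-slice min-max
#'   normalization, sequence identity is carried by relative intensities, so a
#'   slice needs several tissue types in view to be classifiable at all.
#' @return List with tibble `manifest` (columns volume, axis, index, sequence,
#'   split, alpha, label) and `samples`, a list of `slice_sample`s aligned with
#'   the manifest rows (normalized, resized not applied).
#' @export
build_classification_split <- function(volumes_by_sequence, n_slices_per_sequence,
                                       seed = 1L, axis = "axial",
                                       n_test_per_sequence = 2 * n_slices_per_sequence,
                                       min_alpha = 0.25) {
  stop_if(length(volumes_by_sequence) < 1 || is.null(names(volumes_by_sequence)),
          "`volumes_by_sequence` must be a named list.")
  set.seed(seed)
  manifest <- list(); samples <- list()
  seq_names <- names(volumes_by_sequence)
  for (ci in seq_along(seq_names)) {
    sq <- seq_names[ci]
    vols <- volumes_by_sequence[[sq]]
    stop_if(length(vols) < 1, sprintf("no volumes for sequence %s.", sq))
    vol_ids <- names(vols) %||% paste0(sq, "_vol", seq_along(vols))
    # volume-level split: at least one volume reserved for test when possible
    n_train_vols <- if (length(vols) > 1) max(1L, floor(length(vols) / 2)) else 1L
    train_vols <- sample(seq_along(vols), n_train_vols)
    test_vols <- setdiff(seq_along(vols), train_vols)
    if (length(test_vols) == 0L) test_vols <- train_vols  # single-volume fallback
    draw <- function(vol_set, n_want, split) {
      pool <- purrr::map(vol_set, function(vi) {
        n_ax <- dim(vols[[vi]]$image)[3]
        keep <- seq_len(n_ax) - 1L
        if (!is.null(vols[[vi]]$brain_mask) && min_alpha > 0) {
          a <- vapply(seq_len(n_ax), function(i)
            brain_coverage(vols[[vi]]$brain_mask[, , i]), numeric(1))
          keep <- keep[a >= min_alpha]
        }
        tibble::tibble(vi = vi, index = keep)
      })
      pool <- dplyr::bind_rows(pool)
      if (split == "train" && length(test_vols) == length(train_vols) &&
          identical(sort(test_vols), sort(train_vols))) {
        # same single volume for both: split its slices disjointly instead
        pool <- pool[seq_len(floor(nrow(pool) / 2)), ]
      } else if (split == "test" && identical(sort(test_vols), sort(train_vols))) {
        n_ax <- nrow(pool)
        pool <- pool[(floor(n_ax / 2) + 1L):n_ax, ]
      }
      stop_if(nrow(pool) < n_want,
              sprintf("sequence %s: requested %d slices but only %d available.",
                      sq, n_want, nrow(pool)))
      pool[sample(nrow(pool), n_want), ]
    }
    for (split in c("train", "test")) {
      n_want <- if (split == "train") n_slices_per_sequence else n_test_per_sequence
      vol_set <- if (split == "train") train_vols else test_vols
      chosen <- draw(vol_set, n_want, split)
      for (r in seq_len(nrow(chosen))) {
        vol <- vols[[chosen$vi[r]]]
        sl <- extract_slice(vol, 3L, chosen$index[r])
        smp <- slice_sample_new(clamp_normalize(sl$image), brain_mask = sl$brain_mask,
                                labels = sl$labels, sequence_label = ci - 1L,
                                provenance = list(volume = vol_ids[chosen$vi[r]],
                                                  axis = "axial",
                                                  index = chosen$index[r]))
        samples[[length(samples) + 1L]] <- smp
        manifest[[length(manifest) + 1L]] <- dplyr::mutate(
          slice_manifest(list(smp), sequence = sq, split = split), label = ci - 1L)
      }
    }
  }
  list(manifest = dplyr::bind_rows(manifest), samples = samples)
}

#' Volume- or stride-level few-shot split for segmentation
#'
#' For the skull-stripping task, a single volume per sequence is stride-sampled
#' along the acquisition axis (every k-th slice) for training, and held-out
#' volumes (all slices) form the test set. For the anatomy task, whole volumes
#' are sampled for training and remapped to 2D slices along the requested axes
#' with empty-mask filtering.
#'
#' @param volumes Named list of volumes (all same sequence), each with `image`,
#'   `brain_mask` and/or `labels`, and `voxel_size_mm`.
#' @param task `"skull_strip"` or `"anatomy"`.
#' @param stride_k Stride for skull stripping.
#' @param n_volumes Training volumes for the anatomy task.
#' @param axes Axes for tri-axial remapping (anatomy task).
#' @param min_foreground Minimum foreground pixels to keep a slice.
#' @param seed RNG seed.
#' @return List with `manifest` tibble and `train`/`test` lists of
#'   `slice_sample`s (labels for skull stripping are the binary brain mask).
#' @export
build_segmentation_split <- function(volumes, task = c("skull_strip", "anatomy"),
                                     stride_k = 7, n_volumes = 1,
                                     axes = c("sagittal", "coronal", "axial"),
                                     min_foreground = 1, seed = 1L) {
  task <- match.arg(task)
  set.seed(seed)
  vol_ids <- names(volumes) %||% paste0("vol", seq_along(volumes))
  use_mask_labels <- function(v) {
    if (task == "skull_strip") { v$labels <- (v$brain_mask * 1L); storage.mode(v$labels) <- "integer" }
    v
  }
  if (task == "skull_strip") {
    stop_if(length(volumes) < 1, "need at least one volume.")
    tr_vi <- sample(seq_along(volumes), 1L)
    vol <- resample_isotropic(use_mask_labels(volumes[[tr_vi]]))
    n_ax <- dim(vol$image)[3]
    idx <- stride_sample(n_ax, stride_k)
    train <- remap_volume_to_slices(vol, axes = "axial", min_foreground = 0,
                                    volume_id = vol_ids[tr_vi],
                                    indices = list(axial = idx))
    test_vi <- setdiff(seq_along(volumes), tr_vi)
    if (length(test_vi) == 0L) test_vi <- tr_vi  # single-volume smoke runs
    test <- purrr::flatten(purrr::map(test_vi, function(vi) {
      v <- resample_isotropic(use_mask_labels(volumes[[vi]]))
      remap_volume_to_slices(v, axes = "axial", min_foreground = min_foreground,
                             volume_id = vol_ids[vi])
    }))
  } else {
    stop_if(n_volumes > length(volumes) - 1,
            sprintf("requested %d training volumes but only %d volumes available (one must remain for test).",
                    n_volumes, length(volumes)))
    tr_vi <- sample(seq_along(volumes), n_volumes)
    test_vi <- setdiff(seq_along(volumes), tr_vi)
    remap <- function(vi) {
      v <- resample_isotropic(volumes[[vi]])
      remap_volume_to_slices(v, axes = axes, min_foreground = min_foreground,
                             volume_id = vol_ids[vi])
    }
    train <- purrr::flatten(purrr::map(tr_vi, remap))
    test <- purrr::flatten(purrr::map(test_vi, remap))
  }
  manifest <- dplyr::bind_rows(
    slice_manifest(train, split = "train"),
    slice_manifest(test, split = "test")
  )
  list(manifest = manifest, train = train, test = test)
}

#' Write / read a slice manifest CSV
#'
#' @param manifest Tibble from the split builders.
#' @param path CSV path.
#' @return The manifest (read) or `path` invisibly (write).
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) readr::read_csv(path, show_col_types = FALSE)
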