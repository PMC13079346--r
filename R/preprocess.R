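# Slice preprocessing: percentile clamping with min-max normalization,
# aspect-preserving resize to the model input size, seeded augmentation
# (rotation, flips, crop), and isotropic voxel resampling of volumes.

#' Percentile clamp and min-max normalization
#'
#' Values are clipped to the 0.1th-99.9th percentile of the input (linear
#' interpolation between order statistics) and affinely mapped to `[0, 1]`.
#' A constant input maps to all zeros.
#'
#' @param image Numeric array (any shape) of finite values.
#' @param lower,upper Clamping percentiles in `[0, 100]`.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
clamp_normalize <- function(image, lower = 0.1, upper = 99.9) {
  stop_if(!is.numeric(image) || length(image) == 0L, "`image` must be numeric.")
  stop_if(any(!is.finite(image)), "`image` contains NaN or Inf.")
  q <- stats::quantile(image, probs = c(lower, upper) / 100, names = FALSE, type = 7)
  x <- pmin(pmax(image, q[1]), q[2])
  rng <- q[2] - q[1]
  out <- if (rng <= 0) array(0, dim = dim(image) %||% length(image)) else (x - q[1]) / rng
  if (!is.null(dim(image))) dim(out) <- dim(image)
  out
}

pad_to_square <- function(image, value = 0) {
  d <- dim(image)
  if (d[1] == d[2]) return(image)
  n <- max(d)
  out <- matrix(value, n, n)
  r0 <- floor((n - d[1]) / 2); c0 <- floor((n - d[2]) / 2)
  out[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- image
  out
}

resize2d <- function(image, size, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  filt <- if (method == "bilinear") "bilinear" else "none"
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(image), w = size, h = size,
                                            filter = filt))
  matrix(out, size, size)
}

#' Resize a slice (and aligned masks) to the model input size
#'
#' Non-square inputs are first symmetrically zero-padded to square, then
#' resized: the image bilinearly, masks with nearest neighbor so label sets are
#' preserved.
#'
#' @param image 2D numeric array.
#' @param mask Optional 2D mask (binary or integer labels) of the same shape.
#' @param size Output side length (default 224).
#' @return List with `image` (size x size) and `mask` (or `NULL`).
#' @export
resize_to_input <- function(image, mask = NULL, size = 224) {
  stop_if(length(dim(image)) != 2, "`image` must be 2D.")
  if (!is.null(mask)) {
    stop_if(!identical(dim(mask), dim(image)), "`mask` must share the image shape.")
  }
  img <- pad_to_square(image)
  img <- if (all(dim(img) == size)) img else resize2d(img, size, "bilinear")
  msk <- NULL
  if (!is.null(mask)) {
    msk <- pad_to_square(mask * 1)
    msk <- if (all(dim(msk) == size)) msk else resize2d(msk, size, "nearest")
    storage.mode(msk) <- storage.mode(mask * 1L)
  }
  list(image = img, mask = msk)
}

#' Coverage category of a slice
#'
#' @param alpha Brain-coverage fraction in `[0, 1]`.
#' @param partial_below Threshold separating partial from full coverage.
#' @return One of `"empty"`, `"partial"`, `"full"`.
#' @export
coverage_category <- function(alpha, partial_below = 0.25) {
  stop_if(alpha < 0 || alpha > 1, "`alpha` must lie in [0, 1].")
  if (alpha == 0) "empty" else if (alpha < partial_below) "partial" else "full"
}

#' A preprocessed 2D slice sample
#'
#' Bundles a normalized image with optional aligned masks, its sequence label,
#' brain-coverage fraction and provenance.
#'
#' @param image 2D array in `[0, 1]`.
#' @param brain_mask Optional binary 2D mask.
#' @param labels Optional integer 2D label map.
#' @param sequence_label Optional class index in `[0, C)`.
#' @param alpha Coverage fraction; computed from `brain_mask` when available.
#' @param provenance Named list (volume id, axis, slice index).
#' @return A `slice_sample` object.
#' @export
slice_sample_new <- function(image, brain_mask = NULL, labels = NULL,
                             sequence_label = NA_integer_, alpha = NULL,
                             provenance = list()) {
  stop_if(length(dim(image)) != 2, "`image` must be 2D.")
  stop_if(min(image) < 0 || max(image) > 1, "`image` must lie in [0, 1].")
  if (!is.null(brain_mask)) {
    stop_if(!identical(dim(brain_mask), dim(image)), "mask shape mismatch.")
    alpha <- alpha %||% brain_coverage(brain_mask)
  }
  structure(list(image = image, brain_mask = brain_mask, labels = labels,
                 sequence_label = sequence_label, alpha = alpha %||% NA_real_,
                 provenance = provenance),
            class = "slice_sample")
}

rotate2d <- function(image, angle, method = c("bilinear", "nearest"), value = 0) {
  method <- match.arg(method)
  filt <- if (method == "bilinear") "bilinear" else "none"
  out <- EBImage::imageData(EBImage::rotate(EBImage::Image(image), angle,
                                            filter = filt, bg.col = value,
                                            output.dim = dim(image)))
  matrix(out, nrow(image), ncol(image))
}

#' Seeded augmentation of a slice sample
#'
#' Random rotation (uniform in +/- `max_rotation` degrees), independent
#' horizontal/vertical flips (probability `flip_prob` each), and central
#' crop-then-resize (scale uniform in `crop_scale`). The identical geometric
#' transform is applied to the image (bilinear) and any masks (nearest), and
#' the coverage fraction is recomputed from the augmented brain mask.
#'
#' @param sample A `slice_sample`.
#' @param seed RNG seed; the same seed reproduces the same transform.
#' @param enabled If `FALSE`, the sample is returned unchanged.
#' @param max_rotation Degrees; default 15.
#' @param flip_prob Per-axis flip probability; default 0.5.
#' @param crop_scale Length-2 range of the retained central fraction.
#' @return An augmented `slice_sample`.
#' @export
augment_slice <- function(sample, seed, enabled = TRUE, max_rotation = 15,
                          flip_prob = 0.5, crop_scale = c(0.8, 1)) {
  stop_if(!inherits(sample, "slice_sample"), "`sample` must be a slice_sample.")
  if (!enabled) return(sample)
  set.seed(seed)
  angle <- runif(1, -max_rotation, max_rotation)
  flips <- runif(2) < flip_prob
  scale <- runif(1, crop_scale[1], crop_scale[2])
  tf_img <- function(x, method) {
    y <- rotate2d(x, angle, method)
    if (flips[1]) y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
    if (flips[2]) y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
    if (scale < 1) {
      n <- nrow(y)
      keep <- max(2L, round(scale * n))
      o <- floor((n - keep) / 2)
      y <- y[o + seq_len(keep), o + seq_len(keep), drop = FALSE]
      y <- resize2d(y, n, method)
    }
    y
  }
  img <- tf_img(sample$image, "bilinear")
  img[img < 0] <- 0; img[img > 1] <- 1
  bm <- if (!is.null(sample$brain_mask)) tf_img(sample$brain_mask * 1, "nearest")
  lb <- if (!is.null(sample$labels)) {
    z <- tf_img(sample$labels * 1, "nearest"); storage.mode(z) <- "integer"; z
  }
  slice_sample_new(img, brain_mask = bm, labels = lb,
                   sequence_label = sample$sequence_label,
                   provenance = sample$provenance)
}

interp_axis <- function(arr, axis, n_out, method) {
  d <- dim(arr)
  n_in <- d[axis]
  if (n_in == n_out) return(arr)
  # sample centers: map output pixel centers to input coordinates
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  if (method == "nearest") {
    idx <- pmin(pmax(round(pos), 1L), n_in)
    return(index_axis(arr, axis, idx))
  }
  lo <- pmin(pmax(floor(pos), 1L), n_in)
  hi <- pmin(lo + 1L, n_in)
  w <- pmin(pmax(pos - lo, 0), 1)
  a <- index_axis(arr, axis, lo)
  b <- index_axis(arr, axis, hi)
  sweep_shape <- function(x, wts) {
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    xp <- xp * wts
    aperm(xp, order(perm))
  }
  sweep_shape(a, 1 - w) + sweep_shape(b, w)
}

index_axis <- function(arr, axis, idx) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

#' Resample a volume to isotropic voxels
#'
#' Axis lengths are scaled by their voxel-size ratio to the smallest voxel
#' dimension, so a 100-slice axis at 2 mm thickness and 1 mm in-plane becomes
#' 200 slices. The image is interpolated linearly per axis; brain mask and
#' labels use nearest neighbor (label-preserving).
#'
#' @param volume A `phantom_volume` (or any list with `image`, optional
#'   `brain_mask`/`labels`, and `voxel_size_mm`).
#' @return The volume resampled to isotropic voxels.
#' @export
resample_isotropic <- function(volume) {
  vox <- volume$voxel_size_mm
  stop_if(is.null(vox) || any(vox <= 0), "voxel sizes must be positive.")
  target <- min(vox)
  d <- dim(volume$image)
  new_d <- as.integer(round(d * vox / target))
  out <- volume
  for (ax in 1:3) {
    if (new_d[ax] == d[ax]) next
    out$image <- interp_axis(out$image, ax, new_d[ax], "linear")
    if (!is.null(out$brain_mask)) {
      out$brain_mask <- interp_axis(out$brain_mask * 1, ax, new_d[ax], "nearest") > 0.5
    }
    if (!is.null(out$labels)) {
      lb <- interp_axis(out$labels * 1, ax, new_d[ax], "nearest")
      storage.mode(lb) <- "integer"
      out$labels <- lb
    }
    d <- dim(out$image)
  }
  out$voxel_size_mm <- rep(target, 3)
  out
}
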