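test_that("phantom generation is deterministic and shares ground truth across sequences", {
  spec <- phantom_spec(grid_size = 32, seed = 5)
  v1 <- generate_phantom(spec)
  v2 <- generate_phantom(spec)
  expect_identical(v1, v2)
  expect_gt(length(v1), 1)
  for (sq in names(v1)[-1]) {
    expect_identical(v1[[sq]]$brain_mask, v1[[1]]$brain_mask)
    expect_identical(v1[[sq]]$labels, v1[[1]]$labels)
    expect_false(identical(v1[[sq]]$image, v1[[1]]$image))
  }
  expect_identical(v1$T1$brain_mask, v1$T1$labels > 0)
  expect_identical(dim(v1$T1$image), dim(v1$T1$labels))
})

test_that("noiseless rendering produces delta-function tissue histograms", {
  spec <- phantom_spec(grid_size = 32, noise_sd = 0, seed = 2)
  vols <- generate_phantom(spec)
  v <- vols$T2
  lut <- spec$sequences$T2
  # within each brain tissue class the image is exactly the LUT value
  for (k in 1:(spec$n_tissues - 2)) {
    vals <- unique(v$image[v$labels == k])
    expect_length(vals, 1)
    expect_equal(vals, lut[k + 2])  # labels k >= 1 are brain classes (skull removed)
  }
  expect_true(all(v$image[v$labels == 0 & !v$skull_mask] == lut[1]))
})

test_that("noiseless phantoms are perfectly sequence-separable by a nearest-LUT rule", {
  spec <- phantom_spec(grid_size = 32, noise_sd = 0, seed = 8)
  vols <- generate_phantom(spec)
  # render labels including the skull ring to recover per-class intensities
  seqs <- names(vols)
  correct <- 0; total <- 0
  for (sq in seqs) {
    v <- vols[[sq]]
    for (i in seq_len(dim(v$image)[3])) {
      if (brain_coverage(v$brain_mask[, , i]) < 0.25) next
      sl <- v$image[, , i]; lb <- v$labels[, , i]
      obs <- vapply(sort(unique(lb[lb > 0])), function(k) mean(sl[lb == k]), numeric(1))
      score <- vapply(seqs, function(cand) {
        ref <- spec$sequences[[cand]][sort(unique(lb[lb > 0])) + 2]
        sum((obs - ref)^2)
      }, numeric(1))
      correct <- correct + (names(which.min(score)) == sq)
      total <- total + 1
    }
  }
  expect_gt(total, 0)
  expect_equal(correct, total)  # 100% identification at zero noise
})

test_that("coverage profile yields empty, partial and full axial slices", {
  vols <- generate_phantom(phantom_spec(grid_size = 32, seed = 5))
  v <- vols[[1]]
  alphas <- vapply(seq_len(dim(v$brain_mask)[3]),
                   function(i) brain_coverage(v$brain_mask[, , i]), numeric(1))
  cats <- vapply(alphas, coverage_category, character(1))
  expect_setequal(unique(cats), c("empty", "partial", "full"))
})

test_that("brain_coverage is pixel-count arithmetic, invariant to transpose and flips", {
  expect_equal(brain_coverage(matrix(0, 5, 5)), 0)
  expect_equal(brain_coverage(matrix(1, 5, 5)), 1)
  m <- matrix(0L, 224, 224); m[seq_len(12544)] <- 1L
  expect_equal(brain_coverage(m), 0.25)
  set.seed(3)
  r <- matrix(rbinom(24 * 16, 1, .3), 24, 16)
  expect_equal(brain_coverage(t(r)), brain_coverage(r))
  expect_equal(brain_coverage(r[rev(seq_len(nrow(r))), ]), brain_coverage(r))
  expect_equal(brain_coverage(r[, rev(seq_len(ncol(r)))]), brain_coverage(r))
  expect_error(brain_coverage(matrix(numeric(0))), "empty")
  expect_error(brain_coverage(matrix(c(0, 2), 1)), "binary")
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(n_tissues = 1), class = "maefunet_invalid_spec")
  expect_error(phantom_spec(grid_size = 8), "grid_size")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(generate_phantom(list()), class = "maefunet_invalid_spec")
})

test_that("phantoms round-trip through NIfTI with a manifest", {
  vols <- generate_phantom(phantom_spec(grid_size = 16, seed = 1))
  dir <- withr::local_tempdir()
  spec <- phantom_spec(grid_size = 16, seed = 1)
  man <- write_phantom(vols, dir, spec = spec)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_nifti_volume(file.path(dir, man$sequences$T1))
  expect_equal(as.vector(back$data), as.vector(vols$T1$image))
  expect_equal(back$voxel_size_mm, vols$T1$voxel_size_mm, tolerance = 1e-6)
  labs <- read_nifti_volume(file.path(dir, "labels.nii.gz"))
  expect_equal(as.vector(labs$data), as.vector(vols$T1$labels))
})
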