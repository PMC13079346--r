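test_that("stride sampling keeps 1-based multiples of k, floor(n/k) in total", {
  expect_length(stride_sample(224, 7), 32)
  expect_equal(stride_sample(10, 1), 0:9)
  expect_equal(stride_sample(10, 3), c(2L, 5L, 8L))
  expect_length(stride_sample(224, 5), 44)
  expect_identical(length(stride_sample(224, 5)), 2L * length(stride_sample(224, 10)))
  expect_warning(out <- stride_sample(5, 9), "empty")
  expect_length(out, 0)
  # property: count == floor(n/k) over a grid, and indices are in range
  set.seed(12)
  for (i in 1:60) {
    n <- sample(1:1024, 1); k <- sample(1:n, 1)
    idx <- stride_sample(n, k)
    expect_length(idx, floor(n / k))
    expect_true(all(idx >= 0 & idx < n))
    expect_equal(idx, (seq_len(floor(n / k)) * k) - 1L)
  }
})

test_that("volume remapping filters empty-mask slices and is additive over axes", {
  set.seed(4)
  n <- 6
  labels <- array(0L, c(n, n, 5))
  labels[2:4, 2:4, c(1, 3, 4)] <- 1L     # slices 2 and 5 empty along axis 3
  vol <- list(image = array(runif(n * n * 5), c(n, n, 5)), labels = labels,
              voxel_size_mm = c(1, 1, 1))
  kept <- remap_volume_to_slices(vol, axes = "axial", min_foreground = 1)
  expect_length(kept, 3)
  expect_equal(vapply(kept, function(s) s$provenance$index, integer(1)), c(0L, 2L, 3L))

  cube <- list(image = array(runif(4^3), c(4, 4, 4)),
               labels = array(1L, c(4, 4, 4)), voxel_size_mm = c(1, 1, 1))
  ax1 <- remap_volume_to_slices(cube, axes = "axial", min_foreground = 1)
  ax3 <- remap_volume_to_slices(cube, min_foreground = 1)
  expect_length(ax1, 4)
  expect_length(ax3, 3 * 4)
  expect_error(remap_volume_to_slices(list(image = cube$image), min_foreground = 1),
               "labels")
})

test_that("classification split is seeded, sized, and leak-free at the volume level", {
  ph <- tiny_phantoms()
  vbs <- purrr::imap(ph$a, function(v, sq) {
    o <- list(v, ph$b[[sq]]); names(o) <- paste0(sq, c("_a", "_b")); o
  })
  s1 <- build_classification_split(vbs, 10, seed = 3)
  s2 <- build_classification_split(vbs, 10, seed = 3)
  expect_identical(s1$manifest, s2$manifest)
  m <- s1$manifest
  expect_equal(sum(m$split == "train"), 10 * length(vbs))
  # no volume contributes to both splits
  for (sq in unique(m$sequence)) {
    tr_vols <- unique(m$volume[m$sequence == sq & m$split == "train"])
    te_vols <- unique(m$volume[m$sequence == sq & m$split == "test"])
    expect_length(intersect(tr_vols, te_vols), 0)
  }
  # a different seed changes the selection but not the counts
  s3 <- build_classification_split(vbs, 10, seed = 8)
  expect_false(identical(s1$manifest$index, s3$manifest$index))
  expect_equal(dim(s3$manifest), dim(s1$manifest))
  expect_error(build_classification_split(vbs, 10000, seed = 1), "available")
})

test_that("segmentation split stride-samples one volume and recounts in the manifest", {
  ph <- tiny_phantoms()
  sp <- build_segmentation_split(list(p1 = ph$a$T1, p2 = ph$b$T1),
                                 task = "skull_strip", stride_k = 7, seed = 2)
  # 64-slice axis at stride 7 -> floor(64/7) = 9 training slices
  expect_length(sp$train, 9)
  expect_equal(nrow(sp$manifest), length(sp$train) + length(sp$test))
  expect_true(all(vapply(sp$train, function(s) all(s$labels %in% 0:1), logical(1))))

  an <- build_segmentation_split(list(p1 = ph$a$T1, p2 = ph$b$T1),
                                 task = "anatomy", n_volumes = 1, seed = 2,
                                 axes = "axial")
  expect_equal(nrow(an$manifest), length(an$train) + length(an$test))
  expect_true(all(an$manifest$split %in% c("train", "test")))
  expect_error(build_segmentation_split(list(p1 = ph$a$T1), task = "anatomy",
                                        n_volumes = 5, seed = 1), "available")
})

test_that("manifests round-trip through CSV", {
  ph <- tiny_phantoms()
  vbs <- list(T1 = list(a = ph$a$T1, b = ph$b$T1),
              T2 = list(a = ph$a$T2, b = ph$b$T2))
  sp <- build_classification_split(vbs, 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifest(sp$manifest, f)
  back <- read_manifest(f)
  expect_equal(as.data.frame(back), as.data.frame(sp$manifest))
})
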