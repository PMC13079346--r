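test_that("patchify/unpatchify are exact inverses with the documented shapes", {
  img224 <- matrix(stats::runif(224 * 224), 224)
  p <- patchify(img224, 16)
  expect_equal(dim(p), c(196L, 256L))
  expect_identical(unpatchify(p, 224, 16), img224)

  img <- matrix(stats::runif(64 * 64), 64)
  p8 <- patchify(img, 8)
  expect_equal(dim(p8), c(64L, 64L))
  expect_identical(unpatchify(p8, 64, 8), img)

  const <- patchify(matrix(2.5, 32, 32), 8)
  expect_true(all(apply(const, 1, function(r) identical(r, const[1, ]))))
  expect_error(patchify(matrix(0, 30, 30), 16), "divisible")
})

test_that("random masking partitions patches at the configured ratio", {
  plan <- random_mask(196, 0.75, seed = 3)
  expect_length(plan$masked, 147)
  expect_length(plan$kept, 49)
  expect_setequal(c(plan$masked, plan$kept), 0:195)
  expect_length(intersect(plan$masked, plan$kept), 0)
  expect_identical(random_mask(196, 0.75, seed = 3), plan)
  expect_false(identical(random_mask(196, 0.75, seed = 4)$masked, plan$masked))
  expect_error(random_mask(196, 0, seed = 1), "between")
  expect_error(random_mask(196, 1, seed = 1), "between")
})

test_that("coverage weights are a monotone map with floor w_min", {
  expect_equal(coverage_weight(1), 1)
  expect_equal(coverage_weight(0), 0.1)
  grid <- seq(0, 1, by = 0.05)
  w <- coverage_weight(grid)
  expect_true(all(diff(w) > 0))
  expect_true(all(w >= 0.1 & w <= 1))
  expect_equal(coverage_weight(0, w_min = 0.3), 0.3)
  expect_error(coverage_weight(1.2), "0, 1")
})

test_that("masked MSE covers masked patches only", {
  target <- matrix(stats::rnorm(6 * 4), 6, 4)
  plan <- list(masked = c(1L, 4L), kept = c(0L, 2L, 3L, 5L))
  expect_equal(per_sample_masked_mse(target, target, plan), 0)
  # error confined to kept patches contributes nothing
  rec <- target; rec[c(1, 3, 4, 6), ] <- rec[c(1, 3, 4, 6), ] + 5
  expect_equal(per_sample_masked_mse(rec, target, plan), 0)
  # per-patch squared errors 0.04 and 0.16 average to 0.10
  rec2 <- target
  rec2[2, ] <- target[2, ] + 0.2
  rec2[5, ] <- target[5, ] + 0.4
  expect_equal(per_sample_masked_mse(rec2, target, plan), 0.1)
  expect_error(per_sample_masked_mse(rec, target, list(masked = integer(0))), "empty")
})

test_that("weighted batch loss implements the unnormalized weighted mean", {
  expect_equal(weighted_batch_loss(c(3, 5), c(2, 0.1)), 3.25)
  l <- c(0.2, 0.5, 0.9)
  expect_equal(weighted_batch_loss(l), mean(l))
  w <- c(0.3, 1, 0.7)
  expect_equal(weighted_batch_loss(l, 3 * w), 3 * weighted_batch_loss(l, w))
  expect_error(weighted_batch_loss(numeric(0)), "empty")
})

test_that("batch gradient equals the coverage-weighted mean of per-sample gradients", {
  cfg <- micro_vit_config()
  params <- maefunet:::mae_init(cfg, seed = 2)
  set.seed(14)
  imgs <- lapply(1:3, function(i) matrix(stats::runif(16 * 16), 16))
  plans <- lapply(1:3, function(i) random_mask(cfg$n_patches, 0.5, seed = 20 + i))
  alphas <- c(0.1, 0.6, 1)
  w <- coverage_weight(alphas)
  fw <- maefunet:::mae_forward(params, cfg, imgs, plans, alphas)
  g_batch <- maefunet:::flatten_params(maefunet:::mae_backward(params, cfg, fw))
  # per-sample gradients at unit coverage weight (alpha = 1)
  g_sum <- NULL
  for (i in 1:3) {
    fwi <- maefunet:::mae_forward(params, cfg, imgs[i], plans[i], alphas = 1)
    gi <- maefunet:::grads_scale(maefunet:::mae_backward(params, cfg, fwi), w[i] / 3)
    g_sum <- maefunet:::grads_add(g_sum, gi)
  }
  g_sum <- maefunet:::flatten_params(g_sum)
  for (nm in names(g_batch)) {
    denom <- max(1e-12, max(abs(g_batch[[nm]])))
    expect_lt(max(abs(g_batch[[nm]]-g_sum[[nm]])) / denom, 1e-5)
  }
})

test_that("per-sample losses are invariant to batch order", {
  cfg <- micro_vit_config()
  params <- maefunet:::mae_init(cfg, seed = 2)
  set.seed(15)
  imgs <- lapply(1:4, function(i) matrix(stats::runif(16 * 16), 16))
  plans <- lapply(1:4, function(i) random_mask(cfg$n_patches, 0.5, seed = 30 + i))
  a <- c(0.2, 0.4, 0.8, 1)
  l1 <- maefunet:::mae_forward(params, cfg, imgs, plans, a)$l_tilde
  perm <- c(3, 1, 4, 2)
  l2 <- maefunet:::mae_forward(params, cfg, imgs[perm], plans[perm], a[perm])$l_tilde
  expect_equal(l2, l1[perm], tolerance = 1e-12)
})

test_that("pretraining is deterministic and resumable", {
  set.seed(31)
  imgs <- lapply(1:10, function(i) matrix(stats::runif(16 * 16), 16))
  ds <- list(images = imgs, alpha = stats::runif(10), brain_masks = vector("list", 10))
  cfg <- micro_vit_config()
  ck_a <- mae_pretrain(ds, cfg, epochs = 2, batch_size = 5, lr = 1e-3,
                       augment = FALSE, seed = 9)
  ck_b <- mae_pretrain(ds, cfg, epochs = 2, batch_size = 5, lr = 1e-3,
                       augment = FALSE, seed = 9)
  expect_identical(ck_a$params, ck_b$params)
  # resume: 1 epoch then 1 more reproduces the 2-epoch trajectory
  ck_1 <- mae_pretrain(ds, cfg, epochs = 1, batch_size = 5, lr = 1e-3,
                       augment = FALSE, seed = 9)
  ck_12 <- mae_pretrain(ds, cfg, epochs = 1, batch_size = 5, lr = 1e-3,
                        augment = FALSE, seed = 9, resume_from = ck_1)
  expect_equal(ck_12$loss_curve$loss, ck_a$loss_curve$loss, tolerance = 1e-6)
  expect_equal(ck_12$params, ck_a$params, tolerance = 1e-9)
})

test_that("an all-background batch pulls one tenth the gradient of a full-brain batch", {
  cfg <- micro_vit_config()
  params <- maefunet:::mae_init(cfg, seed = 5)
  set.seed(16)
  imgs <- lapply(1:4, function(i) matrix(stats::runif(16 * 16), 16))
  plans <- lapply(1:4, function(i) random_mask(cfg$n_patches, 0.5, seed = 40 + i))
  g0 <- maefunet:::flatten_params(maefunet:::mae_backward(
    params, cfg, maefunet:::mae_forward(params, cfg, imgs, plans, rep(0, 4))))
  g1 <- maefunet:::flatten_params(maefunet:::mae_backward(
    params, cfg, maefunet:::mae_forward(params, cfg, imgs, plans, rep(1, 4))))
  n0 <- sqrt(sum(unlist(g0)^2)); n1 <- sqrt(sum(unlist(g1)^2))
  expect_equal(n0 / n1, 0.1, tolerance = 1e-9)
})

test_that("checkpoints save and load with a JSON sidecar", {
  ck <- micro_checkpoint()
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$params_hash, param_hash(ck$params))
  back <- load_checkpoint(f)
  expect_identical(back$params, ck$params)
})

test_that("config invariants are enforced for both presets", {
  tiny <- vit_config("tiny")
  expect_equal(tiny$image_size %% tiny$patch_size, 0)
  expect_equal(tiny$n_patches, 64)
  base <- vit_config("vitbase")
  expect_equal(base$encoder_layers, 12L)
  expect_equal(base$encoder_dim, 768L)
  expect_equal(base$n_patches, 196)
  expect_error(vit_config("tiny", image_size = 60), "divisible")
})
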