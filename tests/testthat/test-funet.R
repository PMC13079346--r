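# small configs used throughout: 16 px inputs, depth-2 U-Net, width-8 tokens
micro_fc <- function(strategy = "concat", n_classes = 3, base = 4) {
  fusion_config(strategy, tap_layers = c(1, 2, 2), base_channels = base,
                depth = 2, n_classes = n_classes, image_size = 16)
}

micro_taps <- function(N = 2, P = 4, d = 8, seed = 1) {
  set.seed(seed)
  lapply(1:3, function(s) array(stats::rnorm(N * P * d), c(N, P, d)))
}

test_that("the U-Net backbone emits the doubling channel ladder at halving scales", {
  fc <- fusion_config("none", base_channels = 16, depth = 3, n_classes = 2,
                      image_size = 64)
  model <- funet_init(fc, encoder_dim = 64, seed = 1)
  img <- matrix(stats::runif(64 * 64), 64)
  maps <- unet_features(img, model)
  expect_length(maps, 4)
  expect_equal(vapply(maps, function(m) ncol(m$mat), numeric(1)), c(16, 32, 64, 128))
  expect_equal(vapply(maps, function(m) m$H, numeric(1)), c(64, 32, 16, 8))
  # deterministic under fixed weights
  expect_identical(unet_features(img, model)[[4]]$mat, maps[[4]]$mat)
  expect_error(unet_features(matrix(0, 60, 60), model), "divisible")
})

test_that("trainable parameters order add < concat < attention and grow with width", {
  for (cfgs in list(list(taps = c(1, 2, 2), depth = 2, d = 8, img = 16, widths = c(4, 8, 12)),
                    list(taps = c(1, 2, 3, 4), depth = 3, d = 64, img = 64, widths = c(8, 16, 24)))) {
    counts <- vapply(c("add", "concat", "attention"), function(s) {
      n_trainable(funet_init(fusion_config(s, cfgs$taps, 8, cfgs$depth, 2, cfgs$img),
                             encoder_dim = cfgs$d, seed = 1))
    }, numeric(1))
    expect_lt(counts[["add"]], counts[["concat"]])
    expect_lt(counts[["concat"]], counts[["attention"]])
    wcounts <- vapply(cfgs$widths, function(w) {
      n_trainable(funet_init(fusion_config("concat", cfgs$taps, w, cfgs$depth, 2, cfgs$img),
                             encoder_dim = cfgs$d, seed = 1))
    }, numeric(1))
    expect_true(all(diff(wcounts) > 0))
  }
})

test_that("strategy swap changes only fusion-block parameters", {
  shapes <- function(strategy) {
    p <- funet_init(micro_fc(strategy), encoder_dim = 8, seed = 2)$params
    p$fuse <- NULL
    lapply(maefunet:::flatten_params(p), dim)
  }
  expect_identical(shapes("concat"), shapes("add"))
  expect_identical(shapes("concat"), shapes("attention"))
})

test_that("token projection reshapes, projects and resizes as specified", {
  ck <- micro_checkpoint()
  img <- matrix(stats::runif(16 * 16), 16)
  ts <- encode_tokens(ck, img)
  expect_equal(ts$patch_grid, c(2, 2))
  # target at the grid scale: pure channel projection, no resize
  f14 <- project_tokens(ts, layer = 2, out_channels = 5, target_hw = c(2, 2), seed = 1)
  expect_equal(c(f14$H, f14$W, ncol(f14$mat)), c(2, 2, 5))
  # every scale of a ladder gets the right spatial dims
  for (hw in list(c(4, 4), c(8, 8), c(16, 16))) {
    fs <- project_tokens(ts, layer = 1, out_channels = 3, target_hw = hw, seed = 1)
    expect_equal(c(fs$H, fs$W), hw)
  }
  # constant token field stays spatially constant after projection + resize
  st <- ts$per_layer_states[[2]]
  st[] <- rep(seq_len(dim(st)[3]), each = prod(dim(st)[1:2]))
  fc_map <- project_tokens(st, out_channels = 4, target_hw = c(8, 8), seed = 1)
  expect_lt(max(apply(fc_map$mat, 2, function(col) diff(range(col)))), 1e-10)
  expect_error(project_tokens(ts, layer = 99, out_channels = 2, target_hw = c(4, 4)),
               "exceeds")
})

test_that("fusion strategies are drop-in interchangeable with the documented contracts", {
  set.seed(3)
  N <- 2; C <- 6
  f <- maefunet:::fmap(matrix(stats::rnorm(N * 8 * 8 * C), N * 64, C), N, 8L, 8L)
  tok <- array(stats::rnorm(N * 5 * 8), c(N, 5, 8))  # CLS + 4 patch tokens, d = 8
  for (s in c("concat", "add", "attention")) {
    out <- fuse_features(f, tok, strategy = s, grid = c(2, 2), seed = 4)
    expect_equal(ncol(out$mat), C)
    expect_equal(c(out$H, out$W, out$N), c(8L, 8L, N))
  }
  # additive fusion with a zero projection is the identity on the CNN stream
  w0 <- list(Wp = matrix(0, 8, C), bp = numeric(C))
  outa <- fuse_features(f, tok, strategy = "add", grid = c(2, 2), weights = w0)
  expect_equal(outa$mat, f$mat)
})

test_that("dice loss matches the hand-worked two-pixel example and the brute-force oracle", {
  p <- rbind(c(0.8, 0.2), c(0.6, 0.4))
  g <- rbind(c(1, 0), c(1, 0))
  eps <- 1e-5
  hand <- 1 - mean(c((2 * 1.4 + eps) / (1 + 2 + eps), (0 + eps) / (0.2 + 0 + eps)))
  expect_equal(dice_loss(p, g, eps), hand, tolerance = 1e-6)
  expect_equal(dice_loss(p, g, eps), oracle_dice_loss(p, g, eps), tolerance = 1e-12)

  onehot <- diag(3)[c(1, 2, 3, 1), ]
  expect_lt(dice_loss(onehot, onehot), 1e-4)          # perfect overlap
  disj <- onehot[, c(2, 3, 1)]
  expect_gt(dice_loss(disj, onehot), 1 - 1e-4)        # fully disjoint

  rp <- random_prob_target(8 * 8, 3, seed = 5)
  expect_equal(dice_loss(rp$p, rp$g), oracle_dice_loss(rp$p, rp$g), tolerance = 1e-6)
})

test_that("focal loss matches its closed form and decreases in gamma", {
  p1 <- matrix(c(0.5, 0.5), 1)
  g1 <- matrix(c(1, 0), 1)
  expect_equal(focal_loss(p1, g1, gamma = 2, alpha = 0.25),
               0.25 * 0.25 * log(2), tolerance = 1e-9)
  expect_equal(focal_loss(g1, g1), 0)
  gammas <- c(0, 1, 2, 4)
  vals <- vapply(gammas, function(gm) focal_loss(p1, g1, gamma = gm), numeric(1))
  expect_true(all(diff(vals) < 0))
  rp <- random_prob_target(64, 4, seed = 6)
  expect_equal(focal_loss(rp$p, rp$g), oracle_focal_loss(rp$p, rp$g), tolerance = 1e-6)
  expect_equal(pixel_cross_entropy(rp$p, rp$g), oracle_ce_loss(rp$p, rp$g), tolerance = 1e-6)
})

test_that("the hybrid loss is the weighted sum of its three terms", {
  rp <- random_prob_target(32, 3, seed = 7)
  lp <- hybrid_loss_params()
  expect_equal(hybrid_loss(rp$p, rp$g, lp),
               dice_loss(rp$p, rp$g) + focal_loss(rp$p, rp$g) +
                 pixel_cross_entropy(rp$p, rp$g), tolerance = 1e-9)
  only_dice <- hybrid_loss_params(weights = c(dice = 1, focal = 0, ce = 0))
  expect_equal(hybrid_loss(rp$p, rp$g, only_dice), dice_loss(rp$p, rp$g))
  perfect <- diag(3)[rep(1:3, 4), ]
  near <- pmax(pmin(perfect, 1 - 1e-7), 1e-7 / 2)
  near <- near / rowSums(near)
  expect_lt(hybrid_loss(near, perfect, lp), 1e-3)
})

test_that("hybrid-loss gradients match finite differences through the softmax", {
  set.seed(8)
  z <- matrix(stats::rnorm(12 * 3), 12, 3)
  g <- diag(3)[sample(1:3, 12, TRUE), ]
  lp <- hybrid_loss_params()
  hg <- maefunet:::hybrid_grad_logits(z, g, lp, n_samples = 2)
  f <- function(zv) {
    p <- maefunet:::softmax_rows(matrix(zv, 12, 3))
    hybrid_loss(p, g, lp, n_samples = 2)
  }
  idx <- sample(length(z), 8)
  expect_equal(as.vector(hg$dlogits)[idx], numeric_grad(f, as.vector(z), idx),
               tolerance = 1e-5)
  expect_equal(hg$loss, f(as.vector(z)), tolerance = 1e-12)
})

test_that("the direct head upsamples tokens to full resolution with fewer parameters", {
  ck <- micro_checkpoint()
  dm <- mae_direct_init(encoder_dim = 8, grid = 2, image_size = 16, n_classes = 3,
                        seed = 2)
  out <- mae_direct(ck, matrix(stats::runif(16 * 16), 16), model = dm)
  expect_equal(dim(out$labels), c(1L, 16L, 16L))
  expect_true(all(out$labels %in% 0:2))
  out2 <- mae_direct(ck, matrix(out$prob[seq_len(256)], 16), model = dm)
  expect_equal(dim(out2$labels), dim(out$labels))
  fu <- funet_init(micro_fc("concat"), encoder_dim = 8, seed = 1)
  expect_lt(n_trainable(dm), n_trainable(fu))
})

test_that("segmenter training freezes the encoder and the plain U-Net path runs", {
  ck <- micro_checkpoint()
  set.seed(9)
  imgs <- lapply(1:6, function(i) matrix(stats::runif(16 * 16), 16))
  labs <- lapply(imgs, function(m) matrix(as.integer(m > 0.5), 16))
  ds <- list(images = imgs, labels = labs, alpha = rep(1, 6),
             brain_masks = vector("list", 6), sequence_label = rep(NA, 6))
  h0 <- param_hash(ck$params)
  for (s in c("concat", "none")) {
    fit <- train_segmenter(ds, ck, micro_fc(s, n_classes = 2), epochs = 2,
                           batch_size = 3, lr = 1e-3, seed = 2)
    expect_identical(param_hash(ck$params), h0)
    expect_identical(fit$encoder_hash, h0)
    expect_equal(nrow(fit$training_log), 2)
    pr <- predict_segmenter(fit, ck, imgs[1:2])
    expect_equal(dim(pr$labels), c(2L, 16L, 16L))
    expect_equal(unname(rowSums(pr$prob)), rep(1, nrow(pr$prob)), tolerance = 1e-6)
  }
  # direct baseline from the same entry point
  fitd <- train_segmenter(ds, ck, model = "direct", epochs = 2, batch_size = 3,
                          lr = 1e-3, seed = 2)
  expect_identical(param_hash(ck$params), h0)
  expect_error(train_segmenter(list(images = imgs, labels = lapply(labs, function(m) m + 5)),
                               ck, micro_fc("concat", n_classes = 2), epochs = 1, seed = 1),
               "n_classes")
})

test_that("segmenter training is reproducible under a fixed seed", {
  ck <- micro_checkpoint()
  set.seed(10)
  imgs <- lapply(1:4, function(i) matrix(stats::runif(16 * 16), 16))
  labs <- lapply(imgs, function(m) matrix(as.integer(m > 0.5), 16))
  ds <- list(images = imgs, labels = labs)
  f1 <- train_segmenter(ds, ck, micro_fc("add", n_classes = 2), epochs = 2,
                        batch_size = 2, lr = 1e-3, seed = 5)
  f2 <- train_segmenter(ds, ck, micro_fc("add", n_classes = 2), epochs = 2,
                        batch_size = 2, lr = 1e-3, seed = 5)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(f1$training_log, f2$training_log)
})
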