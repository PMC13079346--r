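# finite-difference verification of the hand-written layer gradients

test_that("convolution gradients match finite differences", {
  set.seed(1)
  fm <- maefunet:::fmap(matrix(stats::rnorm(2 * 8 * 8 * 3), 2 * 64, 3), 2L, 8L, 8L)
  W <- maefunet:::he_init(27, 4); b <- stats::rnorm(4)
  fw <- maefunet:::conv3_fwd(fm, W, b)
  dy <- matrix(stats::rnorm(length(fw$out$mat)), nrow(fw$out$mat))
  bw <- maefunet:::conv3_bwd(fw, W, dy)
  idx <- sample(length(W), 6)
  gW <- numeric_grad(function(wv) sum(maefunet:::conv3_fwd(fm, matrix(wv, 27, 4), b)$out$mat * dy),
                     as.vector(W), idx)
  expect_equal(as.vector(bw$dW)[idx], gW, tolerance = 1e-5)
  jdx <- sample(length(fm$mat), 6)
  gX <- numeric_grad(function(xv) {
    sum(maefunet:::conv3_fwd(maefunet:::fmap(matrix(xv, 128, 3), 2L, 8L, 8L), W, b)$out$mat * dy)
  }, as.vector(fm$mat), jdx)
  expect_equal(as.vector(bw$dx)[jdx], gX, tolerance = 1e-5)
})

test_that("maxpool and upsample are mutually consistent gradient pairs", {
  set.seed(2)
  fm <- maefunet:::fmap(matrix(stats::rnorm(128 * 2), 128, 2), 2L, 8L, 8L)
  mp <- maefunet:::maxpool2_fwd(fm)
  expect_equal(c(mp$out$H, mp$out$W), c(4L, 4L))
  dy <- matrix(stats::rnorm(length(mp$out$mat)), nrow(mp$out$mat))
  dx <- maefunet:::maxpool2_bwd(mp$cache, dy)
  idx <- sample(length(fm$mat), 8)
  g <- numeric_grad(function(xv) {
    sum(maefunet:::maxpool2_fwd(maefunet:::fmap(matrix(xv, 128, 2), 2L, 8L, 8L))$out$mat * dy)
  }, as.vector(fm$mat), idx)
  expect_equal(as.vector(dx)[idx], g, tolerance = 1e-4)

  up <- maefunet:::upsample2_fwd(mp$out)
  expect_equal(c(up$H, up$W), c(8L, 8L))
  # nearest upsample backward is the 2x2 block sum
  dyu <- matrix(stats::rnorm(length(up$mat)), nrow(up$mat))
  dxu <- maefunet:::upsample2_bwd(2L, 4L, 4L, dyu)
  gu <- numeric_grad(function(xv) {
    sum(maefunet:::upsample2_fwd(maefunet:::fmap(matrix(xv, 32, 2), 2L, 4L, 4L))$mat * dyu)
  }, as.vector(mp$out$mat), seq_len(6))
  expect_equal(as.vector(dxu)[seq_len(6)], gu, tolerance = 1e-5)
})

test_that("layer norm and attention blocks backpropagate exactly", {
  set.seed(3)
  x <- array(stats::rnorm(2 * 5 * 8), c(2, 5, 8))
  p <- maefunet:::block_init(8)
  fw <- maefunet:::block_fwd(x, p, heads = 2)
  dy <- array(stats::rnorm(length(fw$y)), dim(fw$y))
  bw <- maefunet:::block_bwd(fw$cache, p, dy)
  # input gradient
  idx <- sample(length(x), 8)
  g <- numeric_grad(function(xv) {
    sum(maefunet:::block_fwd(array(xv, dim(x)), p, heads = 2)$y * dy)
  }, as.vector(x), idx)
  expect_equal(as.vector(bw$dx)[idx], g, tolerance = 1e-5)
  # a couple of parameter gradients spanning attention and the MLP
  fp <- maefunet:::flatten_params(p)
  fg <- maefunet:::flatten_params(bw$grads)
  for (nm in c("attn.Wq", "attn.Wo", "mlp_W1", "ln1_g")) {
    i <- sample(length(fp[[nm]]), 2)
    gnum <- numeric_grad(function(v) {
      f2 <- fp; f2[[nm]] <- v
      p2 <- maefunet:::relist_params(f2, p)
      sum(maefunet:::block_fwd(x, p2, heads = 2)$y * dy)
    }, fp[[nm]], i)
    expect_equal(as.vector(fg[[nm]])[i], gnum, tolerance = 1e-5)
  }
})

test_that("the bilinear resize operator preserves constants and transposes cleanly", {
  M <- maefunet:::bilinear_operator(8, 8, 14, 14)
  expect_true(all(abs(Matrix::rowSums(M) - 1) < 1e-12))
  expect_true(all(maefunet:::bilinear_operator(6, 6, 6, 6) - Matrix::Diagonal(36) == 0))
  set.seed(4)
  fm <- maefunet:::fmap(matrix(stats::rnorm(2 * 16 * 3), 32, 3), 2L, 4L, 4L)
  out <- maefunet:::fmap_resize_fwd(fm, 7, 7)
  expect_equal(c(out$H, out$W), c(7, 7))
  dy <- matrix(stats::rnorm(length(out$mat)), nrow(out$mat))
  dx <- maefunet:::fmap_resize_bwd(2L, 4L, 4L, 7L, 7L, dy)
  idx <- sample(length(fm$mat), 6)
  g <- numeric_grad(function(xv) {
    sum(maefunet:::fmap_resize_fwd(maefunet:::fmap(matrix(xv, 32, 3), 2L, 4L, 4L), 7, 7)$mat * dy)
  }, as.vector(fm$mat), idx)
  expect_equal(as.vector(dx)[idx], g, tolerance = 1e-5)
})

test_that("AdamW steps are deterministic and decoupled weight decay shrinks weights", {
  set.seed(5)
  params <- list(W = matrix(stats::rnorm(6), 2, 3), b = numeric(3))
  grads <- list(W = matrix(0, 2, 3), b = numeric(3))
  st <- maefunet:::adamw_init(params)
  out <- maefunet:::adamw_step(params, grads, st, lr = 0.1, weight_decay = 0.5)
  # zero gradient: the update is pure decay, W <- W - lr * wd * W
  expect_equal(out$params$W, params$W * (1 - 0.05))
  out2 <- maefunet:::adamw_step(params, grads, maefunet:::adamw_init(params),
                                lr = 0.1, weight_decay = 0.5)
  expect_identical(out$params, out2$params)
})
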