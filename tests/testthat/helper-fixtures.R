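# Shared fixtures, built once per session on first use. The "tiny" pipeline
# fixtures (phantoms, a pretrained tiny checkpoint) back the end-to-end tests;
# "micro" configs (16 px images, 2-layer width-8 encoder) keep unit tests fast.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  got <- .fixtures[[key]]
  if (!is.null(got)) return(got)
  val <- force(expr)
  assign(key, val, envir = .fixtures)
  val
}

tiny_phantoms <- function() {
  memo("phantoms", {
    list(a = generate_phantom(phantom_spec(grid_size = 64, seed = 11)),
         b = generate_phantom(phantom_spec(grid_size = 64, seed = 12)))
  })
}

tiny_pretrain_dataset <- function() {
  memo("pre_ds", {
    ph <- tiny_phantoms()
    samples <- purrr::flatten(purrr::map(names(ph$a), function(sq) {
      remap_volume_to_slices(ph$a[[sq]], axes = "axial", min_foreground = 0,
                             volume_id = paste0("p1-", sq))
    }))
    as_slice_dataset(samples)
  })
}

# tiny checkpoint shared across the pipeline tests; elapsed time recorded for
# the end-to-end timing check
tiny_checkpoint <- function() {
  memo("ckpt", {
    t0 <- Sys.time()
    ck <- mae_pretrain(tiny_pretrain_dataset(), vit_config("tiny"), epochs = 40,
                       batch_size = 8, lr = 1e-3, seed = 7)
    attr(ck, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ck
  })
}

micro_vit_config <- function() {
  vit_config("tiny", image_size = 16L, patch_size = 8L, encoder_layers = 2L,
             encoder_dim = 8L, heads = 2L, decoder_layers = 1L,
             decoder_dim = 8L, decoder_heads = 2L)
}

micro_checkpoint <- function() {
  memo("micro_ckpt", {
    set.seed(21)
    imgs <- lapply(1:12, function(i) matrix(runif(16 * 16), 16))
    ds <- list(images = imgs, alpha = runif(12), brain_masks = vector("list", 12))
    mae_pretrain(ds, micro_vit_config(), epochs = 2, batch_size = 4, lr = 1e-3,
                 augment = FALSE, seed = 3)
  })
}

numeric_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, numeric(1))
}

## independent brute-force oracles (never call package internals)

oracle_classification <- function(truth, pred, K) {
  f1 <- numeric(K); prec <- numeric(K); rec <- numeric(K); nk <- numeric(K)
  for (k in 0:(K - 1)) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    prec[k + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k + 1] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    nk[k + 1] <- sum(truth == k)
  }
  tp_all <- sum(truth == pred)
  list(accuracy = tp_all / length(truth),
       f1_micro = tp_all / length(truth),
       f1_macro = mean(f1),
       f1_weighted = sum(nk / length(truth) * f1),
       per_class_f1 = f1)
}

oracle_dice_iou <- function(pred, truth) {
  inter <- 0; np <- 0; ng <- 0; uni <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] != 0; g <- truth[i] != 0
    inter <- inter + (p && g)
    np <- np + p; ng <- ng + g
    uni <- uni + (p || g)
  }
  c(dice = 2 * inter / (np + ng), iou = inter / uni)
}

oracle_dice_loss <- function(prob, target, eps = 1e-5) {
  K <- ncol(prob)
  acc <- 0
  for (k in seq_len(K)) {
    num <- eps; den <- eps
    for (i in seq_len(nrow(prob))) {
      num <- num + 2 * prob[i, k] * target[i, k]
      den <- den + prob[i, k]^2 + target[i, k]^2
    }
    acc <- acc + (1 - num / den)
  }
  acc / K
}

oracle_focal_loss <- function(prob, target, gamma = 2, alpha = 0.25) {
  tot <- 0
  for (i in seq_len(nrow(prob))) {
    pt <- max(sum(prob[i, ] * target[i, ]), 1e-12)
    tot <- tot - alpha * (1 - pt)^gamma * log(pt)
  }
  tot / nrow(prob)
}

oracle_ce_loss <- function(prob, target) {
  tot <- 0
  for (i in seq_len(nrow(prob))) {
    pt <- max(sum(prob[i, ] * target[i, ]), 1e-12)
    tot <- tot - log(pt)
  }
  tot / nrow(prob)
}

random_prob_target <- function(npix, K, seed) {
  set.seed(seed)
  z <- matrix(rnorm(npix * K), npix, K)
  p <- exp(z) / rowSums(exp(z))
  g <- matrix(0, npix, K)
  g[cbind(seq_len(npix), sample.int(K, npix, TRUE))] <- 1
  list(p = p, g = g)
}
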