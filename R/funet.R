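# CNN-transformer fusion segmentation. A U-Net backbone (double 3x3 conv +
# ReLU per stage, maxpool down, nearest-upsample + conv up, skip connections)
# is fused with frozen MAE encoder states at the bottleneck and at every
# decoder scale: the deepest tapped layer fuses at the coarsest scale. Fusion
# is concatenation (1x1 channel-reducing conv), addition, or single-head
# cross-attention with CNN features as queries and projected patch tokens as
# keys/values. Trained with a hybrid Dice + Focal + cross-entropy loss; the
# MAE weights stay frozen throughout.

#' Fusion segmenter configuration
#'
#' @param strategy `"concat"`, `"add"`, `"attention"`, or `"none"` (plain
#'   U-Net, no fusion — the backbone ablation).
#' @param tap_layers Encoder layer indices supplying the fused embeddings, one
#'   per decoder scale from finest to coarsest (bottleneck last); length must
#'   be `depth + 1` and no index may exceed the encoder depth.
#' @param base_channels First-stage channel width (32, 64 or 96 at full scale;
#'   16 in the tiny preset).
#' @param depth Number of down/upsampling stages.
#' @param n_classes Segmentation classes (including background).
#' @param image_size Input side length; must be divisible by `2^depth`.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(strategy = c("concat", "add", "attention", "none"),
                          tap_layers = c(1, 3, 6, 9, 12), base_channels = 64,
                          depth = 4, n_classes = 2, image_size = 224) {
  strategy <- match.arg(strategy)
  stop_if(image_size %% 2^depth != 0, "`image_size` must be divisible by 2^depth.")
  if (strategy != "none") {
    stop_if(length(tap_layers) != depth + 1,
            "`tap_layers` must have one entry per decoder scale (depth + 1).")
    stop_if(is.unsorted(tap_layers), "`tap_layers` must be non-decreasing.")
  }
  structure(list(strategy = strategy, tap_layers = as.integer(tap_layers),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size)),
            class = "fusion_config")
}

funet_channels <- function(fc) {
  c(fc$base_channels * 2^(seq_len(fc$depth) - 1), fc$base_channels * 2^fc$depth)
}

conv3_init <- function(cin, cout) list(W = he_init(9 * cin, cout), b = numeric(cout))

#' Initialize a fusion segmenter
#'
#' Builds the trainable parameter set: U-Net backbone, per-scale token
#' projections, fusion blocks for the chosen strategy, and the class head. The
#' MAE encoder itself is not part of the model — its states enter as frozen
#' inputs — so the count of these parameters is the trainable parameter count.
#'
#' @param fc A [fusion_config()].
#' @param encoder_dim Width d of the tapped encoder states.
#' @param seed RNG seed for initialization.
#' @return A `funet_model`: list with `params`, `fc`, `encoder_dim`.
#' @export
funet_init <- function(fc, encoder_dim = 768, seed = 1L) {
  set.seed(seed)
  ch <- funet_channels(fc)
  depth <- fc$depth
  params <- list(enc = list(), dec = list(), fuse = list())
  cin <- 1L
  for (s in seq_len(depth)) {
    params$enc[[s]] <- list(c1 = conv3_init(cin, ch[s]), c2 = conv3_init(ch[s], ch[s]))
    cin <- ch[s]
  }
  params$bott <- list(c1 = conv3_init(ch[depth], ch[depth + 1]),
                      c2 = conv3_init(ch[depth + 1], ch[depth + 1]))
  for (s in seq_len(depth)) {
    cup <- if (s == depth) ch[depth + 1] else ch[s + 1]
    params$dec[[s]] <- list(up = conv3_init(cup, ch[s]),
                            c1 = conv3_init(2 * ch[s], ch[s]),
                            c2 = conv3_init(ch[s], ch[s]))
  }
  if (fc$strategy != "none") {
    for (site in seq_len(depth + 1)) {
      C <- ch[site]
      blk <- list(Wp = xavier_init(encoder_dim, C), bp = numeric(C))
      if (fc$strategy == "concat") {
        blk$Wred <- xavier_init(2 * C, C); blk$bred <- numeric(C)
      } else if (fc$strategy == "attention") {
        blk$Wq <- xavier_init(C, C); blk$bq <- numeric(C)
        blk$Wk <- xavier_init(C, C); blk$bk <- numeric(C)
        blk$Wv <- xavier_init(C, C); blk$bv <- numeric(C)
        blk$Wo <- xavier_init(C, C); blk$bo <- numeric(C)
      }
      params$fuse[[site]] <- blk
    }
    names(params$fuse) <- paste0("S", seq_len(depth + 1))
  }
  params$head <- list(W = xavier_init(ch[1], fc$n_classes), b = numeric(fc$n_classes))
  names(params$enc) <- paste0("S", seq_len(depth))
  names(params$dec) <- paste0("S", seq_len(depth))
  structure(list(params = params, fc = fc, encoder_dim = encoder_dim),
            class = "funet_model")
}

#' Trainable parameter count of a model
#'
#' @param model A `funet_model`, `mae_direct_model`, `probe_head`, or a bare
#'   parameter list.
#' @return Integer parameter count.
#' @export
n_trainable <- function(model) {
  if (inherits(model, "probe_head")) return(model$n_trainable)
  params <- model$params %||% model
  sum(vapply(flatten_params(params), length, numeric(1)))
}

## ---- U-Net encoder --------------------------------------------------------

# returns skips (depth fmaps) + bottleneck fmap, with caches when training
unet_encode <- function(params, fc, x, want_cache = FALSE) {
  skips <- list(); caches <- list()
  for (s in seq_len(fc$depth)) {
    p <- params$enc[[s]]
    f1 <- conv3_fwd(x, p$c1$W, p$c1$b); a1 <- relu_fwd(f1$out$mat)
    fm1 <- fmap(a1, f1$out$N, f1$out$H, f1$out$W)
    f2 <- conv3_fwd(fm1, p$c2$W, p$c2$b); a2 <- relu_fwd(f2$out$mat)
    skip <- fmap(a2, f2$out$N, f2$out$H, f2$out$W)
    mp <- maxpool2_fwd(skip)
    skips[[s]] <- skip
    if (want_cache) caches[[s]] <- list(x1 = x, a1 = a1, fm1 = fm1, a2 = a2, mp = mp$cache)
    x <- mp$out
  }
  p <- params$bott
  f1 <- conv3_fwd(x, p$c1$W, p$c1$b); a1 <- relu_fwd(f1$out$mat)
  fm1 <- fmap(a1, f1$out$N, f1$out$H, f1$out$W)
  f2 <- conv3_fwd(fm1, p$c2$W, p$c2$b); a2 <- relu_fwd(f2$out$mat)
  bott <- fmap(a2, f2$out$N, f2$out$H, f2$out$W)
  if (want_cache) caches$bott <- list(x1 = x, a1 = a1, fm1 = fm1, a2 = a2)
  list(skips = skips, bottleneck = bott, caches = caches)
}

#' Hierarchical CNN feature maps of the U-Net backbone
#'
#' Runs the convolutional encoder and returns the `depth` stage outputs plus
#' the bottleneck: channels `base, 2*base, ..., base*2^depth` at spatial sides
#' `image, image/2, ..., image/2^depth`.
#'
#' @param images `N x H x W` array or list of 2D arrays.
#' @param model A `funet_model`.
#' @return List of feature maps, each a list with `mat` ((N*H*W) x C), `N`,
#'   `H`, `W`.
#' @export
unet_features <- function(images, model) {
  if (is.matrix(images)) images <- list(images)
  if (is.list(images)) {
    arr <- array(0, c(length(images), dim(images[[1]])))
    for (i in seq_along(images)) arr[i, , ] <- images[[i]]
    images <- arr
  }
  stop_if(dim(images)[2] %% 2^model$fc$depth != 0,
          "image side must be divisible by 2^depth.")
  x <- image_batch_to_fmap(images)
  enc <- unet_encode(model$params, model$fc, x)
  c(enc$skips, list(enc$bottleneck))
}

## ---- token projection and fusion -------------------------------------------

# tokens (N, P, d) -> fmap rows ((n-1)*P + q), channels d
tokens_to_fmap_mat <- function(tok) {
  d3 <- dim(tok); N <- d3[1]; P <- d3[2]
  m <- tokens_to_mat(tok)                     # rows: n + (q-1)*N
  qq <- rep(seq_len(P), times = N)
  nn <- rep(seq_len(N), each = P)
  m[nn + (qq - 1L) * N, , drop = FALSE]       # reorder to (n-1)*P + q
}

#' Project encoder patch tokens to a CNN scale
#'
#' Drops the CLS token, linearly maps the `d`-dimensional patch tokens to the
#' target channel width, reshapes them onto the patch grid and bilinearly
#' resizes to the target spatial scale. Constant token fields stay spatially
#' constant.
#'
#' @param states A `token_sequence` (from [encode_tokens()]) or a single
#'   `(N, P+1, d)` layer-state array.
#' @param layer 1-based encoder layer to tap (when `states` is a
#'   `token_sequence`).
#' @param out_channels Channel width at the target scale.
#' @param target_hw Length-2 target spatial dims.
#' @param W,b Projection weights (`d x out_channels`); freshly initialized from
#'   `seed` when omitted.
#' @param seed Seed for the default initialization.
#' @return A feature map (list `mat`, `N`, `H`, `W`).
#' @export
project_tokens <- function(states, layer = NULL, out_channels, target_hw,
                           W = NULL, b = NULL, seed = 1L) {
  if (inherits(states, "token_sequence")) {
    stop_if(is.null(layer), "`layer` required with a token_sequence.")
    stop_if(layer > length(states$per_layer_states), "tap layer exceeds encoder depth.")
    grid <- states$patch_grid
    st <- states$per_layer_states[[layer]]
  } else {
    st <- states
    P <- dim(st)[2] - 1L
    grid <- c(sqrt(P), sqrt(P))
  }
  tok <- st[, -1, , drop = FALSE]             # CLS excluded
  d <- dim(tok)[3]
  if (is.null(W)) { set.seed(seed); W <- xavier_init(d, out_channels) }
  b <- b %||% numeric(out_channels)
  m <- tokens_to_fmap_mat(tok)
  pm <- linear_fwd(m, W, b)
  fm <- fmap(pm, dim(tok)[1], grid[1], grid[2])
  if (!all(c(fm$H, fm$W) == target_hw)) fm <- fmap_resize_fwd(fm, target_hw[1], target_hw[2])
  fm
}

# internal fusion kernels; tok_mat is the projected token matrix ((N*P) x C)
fuse_fwd <- function(f, tok, blk, strategy, grid) {
  N <- f$N; C <- ncol(f$mat); P <- grid[1] * grid[2]
  tok_m <- tokens_to_fmap_mat(tok)
  proj <- linear_fwd(tok_m, blk$Wp, blk$bp)  # (N*P) x C
  if (strategy == "add") {
    pf <- fmap_resize_fwd(fmap(proj, N, grid[1], grid[2]), f$H, f$W)
    out <- fmap(f$mat + pf$mat, N, f$H, f$W)
    cache <- list(tok_m = tok_m)
  } else if (strategy == "concat") {
    pf <- fmap_resize_fwd(fmap(proj, N, grid[1], grid[2]), f$H, f$W)
    cat <- cbind(f$mat, pf$mat)
    red <- linear_fwd(cat, blk$Wred, blk$bred)
    a <- relu_fwd(red)
    out <- fmap(a, N, f$H, f$W)
    cache <- list(tok_m = tok_m, cat = cat, a = a)
  } else { # attention: queries = CNN positions, keys/values = projected tokens
    Q <- linear_fwd(f$mat, blk$Wq, blk$bq)
    K <- linear_fwd(proj, blk$Wk, blk$bk)
    V <- linear_fwd(proj, blk$Wv, blk$bv)
    O <- matrix(0, nrow(f$mat), C)
    A <- vector("list", N)
    HW <- f$H * f$W
    for (n in seq_len(N)) {
      qr <- (n - 1L) * HW + seq_len(HW)
      kr <- (n - 1L) * P + seq_len(P)
      a <- softmax_rows(tcrossprod(Q[qr, , drop = FALSE], K[kr, , drop = FALSE]) / sqrt(C))
      O[qr, ] <- a %*% V[kr, , drop = FALSE]
      A[[n]] <- a
    }
    o2 <- linear_fwd(O, blk$Wo, blk$bo)
    out <- fmap(f$mat + o2, N, f$H, f$W)
    cache <- list(tok_m = tok_m, proj = proj, Q = Q, K = K, V = V, O = O, A = A, P = P)
  }
  list(out = out, cache = c(cache, list(f = f, grid = grid)))
}

fuse_bwd <- function(cache, blk, strategy, dy) {
  f <- cache$f; grid <- cache$grid; N <- f$N; C <- ncol(f$mat)
  if (strategy == "add") {
    dpf <- fmap_resize_bwd(N, grid[1], grid[2], f$H, f$W, dy)
    gp <- linear_bwd(cache$tok_m, blk$Wp, dpf)
    return(list(df = dy, grads = list(Wp = gp$dW, bp = gp$db)))
  }
  if (strategy == "concat") {
    dred <- relu_bwd(cache$a, dy)
    gr <- linear_bwd(cache$cat, blk$Wred, dred)
    df <- gr$dx[, seq_len(C), drop = FALSE]
    dpfm <- gr$dx[, C + seq_len(C), drop = FALSE]
    dproj <- fmap_resize_bwd(N, grid[1], grid[2], f$H, f$W, dpfm)
    gp <- linear_bwd(cache$tok_m, blk$Wp, dproj)
    return(list(df = df, grads = list(Wp = gp$dW, bp = gp$db,
                                      Wred = gr$dW, bred = gr$db)))
  }
  # attention
  P <- cache$P; HW <- f$H * f$W
  go <- linear_bwd(cache$O, blk$Wo, dy)
  dO <- go$dx
  dQ <- matrix(0, nrow(f$mat), C)
  dK <- matrix(0, N * P, C); dV <- dK
  for (n in seq_len(N)) {
    qr <- (n - 1L) * HW + seq_len(HW)
    kr <- (n - 1L) * P + seq_len(P)
    a <- cache$A[[n]]
    dOn <- dO[qr, , drop = FALSE]
    da <- tcrossprod(dOn, cache$V[kr, , drop = FALSE])
    dV[kr, ] <- crossprod(a, dOn)
    ds <- softmax_bwd(a, da) / sqrt(C)
    dQ[qr, ] <- ds %*% cache$K[kr, , drop = FALSE]
    dK[kr, ] <- crossprod(ds, cache$Q[qr, , drop = FALSE])
  }
  gq <- linear_bwd(f$mat, blk$Wq, dQ)
  gk <- linear_bwd(cache$proj, blk$Wk, dK)
  gv <- linear_bwd(cache$proj, blk$Wv, dV)
  dproj <- gk$dx + gv$dx
  gp <- linear_bwd(cache$tok_m, blk$Wp, dproj)
  df <- dy + gq$dx
  list(df = df, grads = list(Wp = gp$dW, bp = gp$db,
                             Wq = gq$dW, bq = gq$db, Wk = gk$dW, bk = gk$db,
                             Wv = gv$dW, bv = gv$db, Wo = go$dW, bo = go$db))
}

#' Fuse a CNN feature map with projected transformer embeddings
#'
#' The three strategies are drop-in interchangeable: each returns a map with
#' the CNN feature map's channel count and spatial dims. Concatenation is
#' followed by a 1x1 channel-reducing convolution (with ReLU); addition sums
#' the aligned maps; attention treats CNN positions as queries over the patch
#' tokens and adds the attended output residually.
#'
#' @param f CNN feature map (list `mat`, `N`, `H`, `W`).
#' @param tokens `(N, P+1, d)` layer-state array (CLS dropped internally).
#' @param strategy `"concat"`, `"add"` or `"attention"`.
#' @param grid Patch-grid dims of the tokens.
#' @param weights Optional fusion block weights (as built by [funet_init()]);
#'   freshly initialized from `seed` when omitted.
#' @param seed Seed for default initialization.
#' @return Fused feature map.
#' @export
fuse_features <- function(f, tokens, strategy = c("concat", "add", "attention"),
                          grid, weights = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  C <- ncol(f$mat); d <- dim(tokens)[3]
  if (is.null(weights)) {
    set.seed(seed)
    weights <- list(Wp = xavier_init(d, C), bp = numeric(C))
    if (strategy == "concat") { weights$Wred <- xavier_init(2 * C, C); weights$bred <- numeric(C) }
    if (strategy == "attention") {
      weights$Wq <- xavier_init(C, C); weights$bq <- numeric(C)
      weights$Wk <- xavier_init(C, C); weights$bk <- numeric(C)
      weights$Wv <- xavier_init(C, C); weights$bv <- numeric(C)
      weights$Wo <- xavier_init(C, C); weights$bo <- numeric(C)
    }
  }
  tok <- tokens[, -1, , drop = FALSE]
  fuse_fwd(f, tok, weights, strategy, grid)$out
}

## ---- full forward/backward --------------------------------------------------

# tap_states: list over fusion sites (1..depth+1) of (N, P, d) arrays (no CLS)
funet_forward <- function(params, fc, x, tap_states, grid, want_cache = FALSE) {
  enc <- unet_encode(params, fc, x, want_cache = want_cache)
  depth <- fc$depth
  fcache <- list()
  h <- enc$bottleneck
  if (fc$strategy != "none") {
    fb <- fuse_fwd(h, tap_states[[depth + 1]], params$fuse[[depth + 1]], fc$strategy, grid)
    h <- fb$out
    if (want_cache) fcache[[depth + 1]] <- fb$cache
  }
  dcache <- list()
  for (s in rev(seq_len(depth))) {
    p <- params$dec[[s]]
    up <- upsample2_fwd(h)
    cu <- conv3_fwd(up, p$up$W, p$up$b); au <- relu_fwd(cu$out$mat)
    upf <- fmap(au, up$N, up$H, up$W)
    cat <- fmap(cbind(enc$skips[[s]]$mat, upf$mat), up$N, up$H, up$W)
    c1 <- conv3_fwd(cat, p$c1$W, p$c1$b); a1 <- relu_fwd(c1$out$mat)
    fm1 <- fmap(a1, up$N, up$H, up$W)
    c2 <- conv3_fwd(fm1, p$c2$W, p$c2$b); a2 <- relu_fwd(c2$out$mat)
    h <- fmap(a2, up$N, up$H, up$W)
    if (want_cache) dcache[[s]] <- list(hin = list(N = cu$x$N %||% NA),
                                        up = up, au = au, upf = upf, cat = cat,
                                        a1 = a1, fm1 = fm1, a2 = a2,
                                        prevHW = c(up$H %/% 2L, up$W %/% 2L),
                                        cu_x = cu$x, c1_x = c1$x, c2_x = c2$x)
    if (fc$strategy != "none") {
      fb <- fuse_fwd(h, tap_states[[s]], params$fuse[[s]], fc$strategy, grid)
      h <- fb$out
      if (want_cache) fcache[[s]] <- fb$cache
    }
  }
  logits <- linear_fwd(h$mat, params$head$W, params$head$b)
  list(logits = logits, out = h,
       cache = if (want_cache) list(enc = enc, dcache = dcache, fcache = fcache,
                                    h_final = h))
}

funet_backward <- function(params, fc, fw, dlogits, tap_states, grid) {
  ch <- fw$cache
  depth <- fc$depth
  grads <- list(enc = vector("list", depth), dec = vector("list", depth),
                fuse = if (fc$strategy != "none") vector("list", depth + 1))
  gh <- linear_bwd(ch$h_final$mat, params$head$W, dlogits)
  grads$head <- list(W = gh$dW, b = gh$db)
  dh <- gh$dx
  dskips <- vector("list", depth)
  for (s in seq_len(depth)) {
    if (fc$strategy != "none") {
      fb <- fuse_bwd(ch$fcache[[s]], params$fuse[[s]], fc$strategy, dh)
      grads$fuse[[s]] <- fb$grads
      dh <- fb$df
    }
    dc <- ch$dcache[[s]]
    da2 <- relu_bwd(dc$a2, dh)
    g2 <- conv3_bwd(list(x = dc$c2_x), params$dec[[s]]$c2$W, da2)
    da1 <- relu_bwd(dc$a1, g2$dx)
    g1 <- conv3_bwd(list(x = dc$c1_x), params$dec[[s]]$c1$W, da1)
    Cs <- ncol(ch$enc$skips[[s]]$mat)
    dskips[[s]] <- g1$dx[, seq_len(Cs), drop = FALSE]
    dupf <- g1$dx[, Cs + seq_len(ncol(dc$upf$mat)), drop = FALSE]
    dau <- relu_bwd(dc$au, dupf)
    gu <- conv3_bwd(list(x = dc$cu_x), params$dec[[s]]$up$W, dau)
    dh <- upsample2_bwd(dc$up$N, dc$prevHW[1], dc$prevHW[2], gu$dx)
    grads$dec[[s]] <- list(up = list(W = gu$dW, b = gu$db),
                           c1 = list(W = g1$dW, b = g1$db),
                           c2 = list(W = g2$dW, b = g2$db))
  }
  if (fc$strategy != "none") {
    fb <- fuse_bwd(ch$fcache[[depth + 1]], params$fuse[[depth + 1]], fc$strategy, dh)
    grads$fuse[[depth + 1]] <- fb$grads
    dh <- fb$df
  }
  # bottleneck
  bc <- ch$enc$caches$bott
  da2 <- relu_bwd(bc$a2, dh)
  g2 <- conv3_bwd(list(x = bc$fm1), params$bott$c2$W, da2)
  da1 <- relu_bwd(bc$a1, g2$dx)
  g1 <- conv3_bwd(list(x = bc$x1), params$bott$c1$W, da1)
  grads$bott <- list(c1 = list(W = g1$dW, b = g1$db), c2 = list(W = g2$dW, b = g2$db))
  dh <- g1$dx
  for (s in rev(seq_len(depth))) {
    sc <- ch$enc$caches[[s]]
    dskip <- maxpool2_bwd(sc$mp, dh) + dskips[[s]]
    da2 <- relu_bwd(sc$a2, dskip)
    g2 <- conv3_bwd(list(x = sc$fm1), params$enc[[s]]$c2$W, da2)
    da1 <- relu_bwd(sc$a1, g2$dx)
    g1 <- conv3_bwd(list(x = sc$x1), params$enc[[s]]$c1$W, da1)
    grads$enc[[s]] <- list(c1 = list(W = g1$dW, b = g1$db), c2 = list(W = g2$dW, b = g2$db))
    dh <- g1$dx
  }
  names(grads$enc) <- paste0("S", seq_len(depth))
  names(grads$dec) <- paste0("S", seq_len(depth))
  if (fc$strategy != "none") names(grads$fuse) <- paste0("S", seq_len(depth + 1))
  grads
}

## ---- segmentation losses -----------------------------------------------------

as_prob_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  stop_if(is.null(dim(x)), "probabilities must be a matrix (pixels x classes).")
  matrix(x, prod(dim(x)[-length(dim(x))]), dim(x)[length(dim(x))])
}

#' Soft Dice loss (per-sample, background included)
#'
#' For each sample and class: `1 - (2*sum(p*g) + eps) / (sum(p^2) + sum(g^2) + eps)`
#' averaged over classes (background included) and then over samples.
#'
#' @param prob Pixel-class probability matrix (`n_pixels x K`, rows summing to
#'   1); pixels of all samples stacked contiguously.
#' @param target One-hot target matrix of the same shape.
#' @param epsilon Smoothing constant (default 1e-5).
#' @param n_samples Number of equally sized samples stacked in `prob`.
#' @return Scalar loss.
#' @export
dice_loss <- function(prob, target, epsilon = 1e-5, n_samples = 1) {
  prob <- as_prob_matrix(prob); target <- as_prob_matrix(target)
  stop_if(!all(dim(prob) == dim(target)), "shape mismatch.")
  npix <- nrow(prob) / n_samples
  total <- 0
  for (n in seq_len(n_samples)) {
    rows <- (n - 1) * npix + seq_len(npix)
    p <- prob[rows, , drop = FALSE]; g <- target[rows, , drop = FALSE]
    num <- 2 * colSums(p * g) + epsilon
    den <- colSums(p * p) + colSums(g * g) + epsilon
    total <- total + (1 - mean(num / den))
  }
  total / n_samples
}

dice_grad <- function(prob, target, epsilon = 1e-5, n_samples = 1) {
  npix <- nrow(prob) / n_samples
  K <- ncol(prob)
  G <- matrix(0, nrow(prob), K)
  for (n in seq_len(n_samples)) {
    rows <- (n - 1) * npix + seq_len(npix)
    p <- prob[rows, , drop = FALSE]; g <- target[rows, , drop = FALSE]
    num <- 2 * colSums(p * g) + epsilon
    den <- colSums(p * p) + colSums(g * g) + epsilon
    # d(1 - num/den)/dp_i = -(2 g_i * den - num * 2 p_i) / den^2
    G[rows, ] <- -sweep(sweep(2 * g, 2, den, `*`) - sweep(2 * p, 2, num, `*`),
                        2, den^2, `/`) / (K * n_samples)
  }
  G
}

#' Focal loss
#'
#' Mean over pixels of `-alpha * (1 - p_true)^gamma * log(p_true)`; the
#' modulating factor down-weights well-classified pixels. `p_true` is clamped
#' at 1e-12 before the logarithm.
#'
#' @param prob Probability matrix (`n_pixels x K`).
#' @param target One-hot target matrix.
#' @param gamma Focusing exponent (default 2).
#' @param alpha Scalar weight (default 0.25), applied uniformly to all classes.
#' @return Scalar loss.
#' @export
focal_loss <- function(prob, target, gamma = 2, alpha = 0.25) {
  prob <- as_prob_matrix(prob); target <- as_prob_matrix(target)
  stop_if(!all(dim(prob) == dim(target)), "shape mismatch.")
  pt <- pmax(rowSums(prob * target), 1e-12)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

focal_grad <- function(prob, target, gamma = 2, alpha = 0.25) {
  pt <- pmax(rowSums(prob * target), 1e-12)
  dpt <- alpha * (gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt) / nrow(prob)
  target * dpt
}

#' Pixel-wise multi-class cross-entropy
#'
#' Mean over pixels of `-log(p_true)` with the same 1e-12 clamp as the focal
#' term.
#'
#' @inheritParams focal_loss
#' @return Scalar loss.
#' @export
pixel_cross_entropy <- function(prob, target) {
  prob <- as_prob_matrix(prob); target <- as_prob_matrix(target)
  pt <- pmax(rowSums(prob * target), 1e-12)
  mean(-log(pt))
}

ce_grad <- function(prob, target) {
  pt <- pmax(rowSums(prob * target), 1e-12)
  target * (-1 / (pt * nrow(prob)))
}

#' Hybrid segmentation loss
#'
#' Weighted sum of the soft Dice, focal and pixel-wise cross-entropy terms
#' (unit weights by default).
#'
#' @inheritParams dice_loss
#' @param params List with `epsilon`, `gamma`, `focal_alpha` and `weights`
#'   (named dice/focal/ce); see [hybrid_loss_params()].
#' @return Scalar loss.
#' @export
hybrid_loss <- function(prob, target, params = hybrid_loss_params(), n_samples = 1) {
  w <- params$weights
  w[["dice"]] * dice_loss(prob, target, params$epsilon, n_samples) +
    w[["focal"]] * focal_loss(prob, target, params$gamma, params$focal_alpha) +
    w[["ce"]] * pixel_cross_entropy(prob, target)
}

#' @rdname hybrid_loss
#' @param epsilon,gamma,focal_alpha Term constants.
#' @param weights Named term weights.
#' @export
hybrid_loss_params <- function(epsilon = 1e-5, gamma = 2, focal_alpha = 0.25,
                               weights = c(dice = 1, focal = 1, ce = 1)) {
  stop_if(epsilon <= 0, "`epsilon` must be positive.")
  stop_if(gamma < 0, "`gamma` must be >= 0.")
  list(epsilon = epsilon, gamma = gamma, focal_alpha = focal_alpha, weights = weights)
}

hybrid_grad_logits <- function(logits, target, params, n_samples) {
  p <- softmax_rows(logits)
  w <- params$weights
  G <- w[["dice"]] * dice_grad(p, target, params$epsilon, n_samples) +
    w[["focal"]] * focal_grad(p, target, params$gamma, params$focal_alpha) +
    w[["ce"]] * ce_grad(p, target)
  list(loss = w[["dice"]] * dice_loss(p, target, params$epsilon, n_samples) +
         w[["focal"]] * focal_loss(p, target, params$gamma, params$focal_alpha) +
         w[["ce"]] * pixel_cross_entropy(p, target),
       dlogits = softmax_bwd(p, G))
}

## ---- MAE-direct baseline ------------------------------------------------------

#' Initialize the direct segmentation head
#'
#' Baseline that attaches a convolutional upsampling head straight to the
#' final-layer patch tokens, with no feature fusion: repeated
#' (2x nearest upsample + 3x3 conv + ReLU) blocks halve the channel width from
#' `d` down to the full resolution, followed by a 1x1 class head.
#'
#' @param encoder_dim Token width d.
#' @param grid Patch grid side length.
#' @param image_size Output side length.
#' @param n_classes Segmentation classes.
#' @param seed RNG seed.
#' @return An `mae_direct_model`.
#' @export
mae_direct_init <- function(encoder_dim, grid, image_size, n_classes, seed = 1L) {
  set.seed(seed)
  n_up <- round(log2(image_size / grid))
  stop_if(grid * 2^n_up != image_size, "image size must be grid * 2^k.")
  cin <- encoder_dim
  blocks <- list()
  for (i in seq_len(n_up)) {
    cout <- max(8L, cin %/% 2L)
    blocks[[i]] <- conv3_init(cin, cout)
    cin <- cout
  }
  names(blocks) <- paste0("B", seq_len(n_up))
  params <- list(blocks = blocks,
                 head = list(W = xavier_init(cin, n_classes), b = numeric(n_classes)))
  structure(list(params = params, encoder_dim = encoder_dim, grid = grid,
                 image_size = image_size, n_classes = n_classes),
            class = "mae_direct_model")
}

mae_direct_forward <- function(model, tok, want_cache = FALSE) {
  # tok: (N, P, d) final-layer states without CLS
  N <- dim(tok)[1]
  x <- fmap(tokens_to_fmap_mat(tok), N, model$grid, model$grid)
  caches <- list()
  for (i in seq_along(model$params$blocks)) {
    up <- upsample2_fwd(x)
    cv <- conv3_fwd(up, model$params$blocks[[i]]$W, model$params$blocks[[i]]$b)
    a <- relu_fwd(cv$out$mat)
    if (want_cache) caches[[i]] <- list(up = up, cv_x = cv$x, a = a,
                                        prevHW = c(x$H, x$W))
    x <- fmap(a, up$N, up$H, up$W)
  }
  logits <- linear_fwd(x$mat, model$params$head$W, model$params$head$b)
  list(logits = logits, out = x, caches = caches)
}

mae_direct_backward <- function(model, fw, dlogits) {
  gh <- linear_bwd(fw$out$mat, model$params$head$W, dlogits)
  grads <- list(blocks = vector("list", length(model$params$blocks)),
                head = list(W = gh$dW, b = gh$db))
  dh <- gh$dx
  for (i in rev(seq_along(model$params$blocks))) {
    cc <- fw$caches[[i]]
    da <- relu_bwd(cc$a, dh)
    g <- conv3_bwd(list(x = cc$cv_x), model$params$blocks[[i]]$W, da)
    dh <- upsample2_bwd(cc$up$N, cc$prevHW[1], cc$prevHW[2], g$dx)
    grads$blocks[[i]] <- list(W = g$dW, b = g$db)
  }
  names(grads$blocks) <- paste0("B", seq_along(grads$blocks))
  grads
}

#' Direct segmentation from frozen tokens
#'
#' @param checkpoint Frozen `mae_checkpoint`.
#' @param images Input slices (list or `N x H x W` array).
#' @param model An `mae_direct_model` (initialized from `seed` when omitted).
#' @param n_classes Classes when auto-initializing.
#' @param seed Seed for auto-initialization.
#' @return List with `labels` (`N x H x W` integer array, lowest-index
#'   tie-break) and `prob` (pixel-class matrix), plus the model used.
#' @export
mae_direct <- function(checkpoint, images, model = NULL, n_classes = 2, seed = 1L) {
  cfg <- checkpoint$config
  if (is.null(model)) {
    model <- mae_direct_init(cfg$encoder_dim, cfg$grid, cfg$image_size, n_classes, seed)
  }
  ts <- encode_tokens(checkpoint, images)
  tok <- ts$tokens[, -1, , drop = FALSE]
  fw <- mae_direct_forward(model, tok)
  p <- softmax_rows(fw$logits)
  lab <- max.col(p, ties.method = "first") - 1L
  N <- dim(tok)[1]
  labs <- fmap_to_image_batch(fmap(matrix(as.numeric(lab), ncol = 1),
                                   N, model$image_size, model$image_size))
  storage.mode(labs) <- "integer"
  list(labels = labs, prob = p, model = model)
}

## ---- training ------------------------------------------------------------------

labels_to_fmap_rows <- function(labels_list) {
  # each labels matrix H x W -> row-major vector; stack samples
  unlist(lapply(labels_list, function(m) as.integer(t(m))), use.names = FALSE)
}

tap_states_for <- function(checkpoint, fc, images) {
  ts <- encode_tokens(checkpoint, images)
  lapply(fc$tap_layers, function(l) {
    stop_if(l > length(ts$per_layer_states), "tap layer exceeds encoder depth.")
    ts$per_layer_states[[l]][, -1, , drop = FALSE]
  })
}

#' Train a segmenter on frozen MAE features
#'
#' Trains the U-Net + fusion + head parameters (or the direct head for
#' `model = "direct"`, or a plain U-Net for strategy `"none"`) with AdamW on
#' the hybrid loss; the MAE encoder is used forward-only, and its states for
#' the training slices are computed once and cached. Deterministic under a
#' fixed seed.
#'
#' @param dataset Slice dataset (see [as_slice_dataset()]) with `labels` set
#'   (integer maps; for skull stripping, the binary brain mask).
#' @param checkpoint Frozen `mae_checkpoint`.
#' @param fc A [fusion_config()] (ignored for `model = "direct"`).
#' @param model `"funet"` (default) or `"direct"`.
#' @param epochs,batch_size,lr,weight_decay AdamW settings.
#' @param loss_params See [hybrid_loss_params()].
#' @param seed RNG seed.
#' @param verbose Print per-epoch loss?
#' @param val_dataset Optional held-out dataset; mean foreground Dice is logged
#'   per epoch.
#' @return A `segmenter_fit`: list with `model` (trained), `kind`, `fc`,
#'   `training_log` tibble (epoch, loss, optional val_dice), `encoder_hash`.
#' @export
train_segmenter <- function(dataset, checkpoint, fc = NULL, model = c("funet", "direct"),
                            epochs = 20, batch_size = 8, lr = 1e-3,
                            weight_decay = 1e-4,
                            loss_params = hybrid_loss_params(), seed = 1L,
                            verbose = FALSE, val_dataset = NULL) {
  kind <- match.arg(model)
  cfg <- checkpoint$config
  n <- length(dataset$images)
  stop_if(n == 0L, "empty dataset.")
  stop_if(any(vapply(dataset$labels, is.null, logical(1))), "labels required.")
  n_classes <- if (kind == "funet") fc$n_classes else NULL
  max_lab <- max(vapply(dataset$labels, max, numeric(1)))
  if (kind == "funet") {
    stop_if(max_lab >= fc$n_classes, "label index >= n_classes.")
    stop_if(fc$image_size != cfg$image_size, "fusion config/image size mismatch.")
    net <- funet_init(fc, encoder_dim = cfg$encoder_dim,
                      seed = derive_seed(seed, "funet-init"))
  } else {
    n_classes <- as.integer(max_lab) + 1L
    net <- mae_direct_init(cfg$encoder_dim, cfg$grid, cfg$image_size, n_classes,
                           seed = derive_seed(seed, "direct-init"))
    fc <- fc %||% NULL
  }
  K <- if (kind == "funet") fc$n_classes else n_classes
  enc_hash <- param_hash(checkpoint$params)
  # frozen-encoder states computed once per slice
  if (kind == "funet" && fc$strategy != "none") {
    taps <- tap_states_for(checkpoint, fc, dataset$images)
  } else if (kind == "direct") {
    ts <- encode_tokens(checkpoint, dataset$images)
    tok_all <- ts$tokens[, -1, , drop = FALSE]
  }
  labs <- dataset$labels
  opt <- adamw_init(net$params)
  log_rows <- list()
  H <- cfg$image_size
  for (ep in seq_len(epochs)) {
    set.seed(derive_seed(seed, "seg-shuffle", ep))
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = batch_size)) {
      ids <- ord[b0:min(b0 + batch_size - 1L, n)]
      N <- length(ids)
      imgs <- array(0, c(N, H, H))
      for (j in seq_len(N)) imgs[j, , ] <- dataset$images[[ids[j]]]
      yv <- labels_to_fmap_rows(labs[ids])
      target <- matrix(0, length(yv), K)
      target[cbind(seq_along(yv), yv + 1L)] <- 1
      if (kind == "funet") {
        tap_b <- if (fc$strategy == "none") NULL else
          lapply(taps, function(a) a[ids, , , drop = FALSE])
        x <- image_batch_to_fmap(imgs)
        fw <- funet_forward(net$params, fc, x, tap_b, c(cfg$grid, cfg$grid),
                            want_cache = TRUE)
        hg <- hybrid_grad_logits(fw$logits, target, loss_params, N)
        gr <- funet_backward(net$params, fc, fw, hg$dlogits, tap_b,
                             c(cfg$grid, cfg$grid))
      } else {
        tok_b <- tok_all[ids, , , drop = FALSE]
        fw <- mae_direct_forward(net, tok_b, want_cache = TRUE)
        hg <- hybrid_grad_logits(fw$logits, target, loss_params, N)
        gr <- mae_direct_backward(net, fw, hg$dlogits)
      }
      st <- adamw_step(net$params, gr, opt, lr = lr, weight_decay = weight_decay)
      net$params <- st$params; opt <- st$state
      ep_loss <- ep_loss + hg$loss; nb <- nb + 1L
    }
    row <- tibble::tibble(epoch = ep, loss = ep_loss / nb)
    if (!is.null(val_dataset)) {
      pred <- predict_segmenter(list(model = net, kind = kind, fc = fc), checkpoint,
                                val_dataset$images)
      dices <- vapply(seq_along(val_dataset$labels), function(i) {
        multiclass_dice_iou(pred$labels[i, , ], val_dataset$labels[[i]], K)$mean_dice
      }, numeric(1))
      row$val_dice <- mean(dices)
    }
    log_rows[[ep]] <- row
    if (verbose) message(sprintf("epoch %d: loss %.5f", ep, ep_loss / nb))
  }
  structure(list(model = net, kind = kind, fc = fc,
                 training_log = dplyr::bind_rows(log_rows),
                 encoder_hash = enc_hash, seed = seed),
            class = "segmenter_fit")
}

#' Predict label maps from a trained segmenter
#'
#' @param fit A `segmenter_fit` (or list with `model`, `kind`, `fc`).
#' @param checkpoint The frozen `mae_checkpoint` used in training.
#' @param images Input slices.
#' @return List with `labels` (`N x H x W` integer array) and `prob` matrix.
#' @export
predict_segmenter <- function(fit, checkpoint, images) {
  cfg <- checkpoint$config
  if (is.list(images) || is.matrix(images)) {
    if (is.matrix(images)) images <- list(images)
    arr <- array(0, c(length(images), dim(images[[1]])))
    for (i in seq_along(images)) arr[i, , ] <- images[[i]]
    images <- arr
  }
  N <- dim(images)[1]
  if (fit$kind == "funet") {
    taps <- if (fit$fc$strategy == "none") NULL else
      tap_states_for(checkpoint, fit$fc, images)
    x <- image_batch_to_fmap(images)
    fw <- funet_forward(fit$model$params, fit$fc, x, taps, c(cfg$grid, cfg$grid))
    p <- softmax_rows(fw$logits)
    H <- fit$fc$image_size
  } else {
    ts <- encode_tokens(checkpoint, images)
    fw <- mae_direct_forward(fit$model, ts$tokens[, -1, , drop = FALSE])
    p <- softmax_rows(fw$logits)
    H <- fit$model$image_size
  }
  lab <- max.col(p, ties.method = "first") - 1L
  labs <- fmap_to_image_batch(fmap(matrix(as.numeric(lab), ncol = 1), N, H, H))
  storage.mode(labs) <- "integer"
  list(labels = labs, prob = p)
}

#' @export
tidy.segmenter_fit <- function(x, ...) x$training_log

#' @export
glance.segmenter_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind,
                 strategy = if (!is.null(x$fc)) x$fc$strategy else NA_character_,
                 n_trainable = n_trainable(x$model),
                 final_loss = utils::tail(x$training_log$loss, 1))
}
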