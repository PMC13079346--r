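# Minimal neural-network primitives with explicit forward/backward passes.
# All dense math is delegated to BLAS matrix products; feature maps are stored
# as (N*H*W) x C matrices in sample-major, row-major pixel order, and token
# tensors as (N, T, d) arrays. Every forward returns the quantities its
# backward needs; gradients are exact (verified against finite differences in
# the test suite).

## ---- initializers ------------------------------------------------------

he_init <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

xavier_init <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, 0, sqrt(1 / fan_in)), fan_in, fan_out)
}

## ---- dense -------------------------------------------------------------

linear_fwd <- function(x, W, b = NULL) {
  y <- x %*% W
  if (!is.null(b)) y <- sweep(y, 2, b, `+`)
  y
}

linear_bwd <- function(x, W, dy) {
  list(dW = crossprod(x, dy), db = colSums(dy), dx = tcrossprod(dy, W))
}

## ---- layer norm (over the feature/last dimension of a matrix) ----------

layernorm_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, g, `*`)
  y <- sweep(y, 2, b, `+`)
  list(y = y, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, g, dy) {
  xhat <- cache$xhat; inv <- cache$inv
  d <- ncol(xhat)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, `*`)
  # dx = inv/d * (d*dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dx <- (dxhat - (s1 + xhat * s2) / d) * inv
  list(dx = dx, dg = dg, db = db)
}

## ---- activations -------------------------------------------------------

gelu_fwd <- function(x) x * stats::pnorm(x)

gelu_bwd <- function(x, dy) dy * (stats::pnorm(x) + x * stats::dnorm(x))

relu_fwd <- function(x) { x[x < 0] <- 0; x }

relu_bwd <- function(y, dy) { dy[y <= 0] <- 0; dy }

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# gradient through row-wise softmax: given p = softmax(z) and dL/dp
softmax_bwd <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

## ---- multi-head self-attention on (N, T, d) token arrays ----------------

mha_init <- function(d, seed_offset = 0) {
  list(Wq = xavier_init(d, d), bq = numeric(d),
       Wk = xavier_init(d, d), bk = numeric(d),
       Wv = xavier_init(d, d), bv = numeric(d),
       Wo = xavier_init(d, d), bo = numeric(d))
}

tokens_to_mat <- function(x) {
  d3 <- dim(x)
  matrix(x, d3[1] * d3[2], d3[3])
}

mat_to_tokens <- function(m, N, T) array(m, c(N, T, ncol(m)))

mha_fwd <- function(x, p, heads) {
  d3 <- dim(x); N <- d3[1]; T <- d3[2]; d <- d3[3]
  dh <- d %/% heads
  xm <- tokens_to_mat(x)
  Q <- linear_fwd(xm, p$Wq, p$bq)
  K <- linear_fwd(xm, p$Wk, p$bk)
  V <- linear_fwd(xm, p$Wv, p$bv)
  O <- matrix(0, N * T, d)
  A <- vector("list", N)
  for (n in seq_len(N)) {
    rows <- n + (seq_len(T) - 1L) * N   # (N,T,d) flattening: sample index fastest
    An <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      a <- softmax_rows(tcrossprod(Q[rows, cols, drop = FALSE],
                                   K[rows, cols, drop = FALSE]) / sqrt(dh))
      O[rows, cols] <- a %*% V[rows, cols, drop = FALSE]
      An[[h]] <- a
    }
    A[[n]] <- An
  }
  y <- linear_fwd(O, p$Wo, p$bo)
  list(y = mat_to_tokens(y, N, T), cache = list(xm = xm, Q = Q, K = K, V = V,
                                                O = O, A = A, N = N, T = T,
                                                heads = heads, dh = dh))
}

mha_bwd <- function(cache, p, dy) {
  N <- cache$N; T <- cache$T; heads <- cache$heads; dh <- cache$dh
  dym <- tokens_to_mat(dy)
  go <- linear_bwd(cache$O, p$Wo, dym)
  dO <- go$dx
  dQ <- matrix(0, N * T, heads * dh)
  dK <- dQ; dV <- dQ
  for (n in seq_len(N)) {
    rows <- n + (seq_len(T) - 1L) * N
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      a <- cache$A[[n]][[h]]
      dOn <- dO[rows, cols, drop = FALSE]
      Vn <- cache$V[rows, cols, drop = FALSE]
      da <- tcrossprod(dOn, Vn)
      dV[rows, cols] <- crossprod(a, dOn)
      ds <- softmax_bwd(a, da) / sqrt(dh)
      dQ[rows, cols] <- ds %*% cache$K[rows, cols, drop = FALSE]
      dK[rows, cols] <- crossprod(ds, cache$Q[rows, cols, drop = FALSE])
    }
  }
  gq <- linear_bwd(cache$xm, p$Wq, dQ)
  gk <- linear_bwd(cache$xm, p$Wk, dK)
  gv <- linear_bwd(cache$xm, p$Wv, dV)
  dx <- gq$dx + gk$dx + gv$dx
  list(dx = mat_to_tokens(dx, N, T),
       grads = list(Wq = gq$dW, bq = gq$db, Wk = gk$dW, bk = gk$db,
                    Wv = gv$dW, bv = gv$db, Wo = go$dW, bo = go$db))
}

## ---- transformer block (pre-LN) -----------------------------------------

block_init <- function(d, mlp_ratio = 4) {
  list(ln1_g = rep(1, d), ln1_b = numeric(d),
       attn = mha_init(d),
       ln2_g = rep(1, d), ln2_b = numeric(d),
       mlp_W1 = xavier_init(d, mlp_ratio * d), mlp_b1 = numeric(mlp_ratio * d),
       mlp_W2 = xavier_init(mlp_ratio * d, d), mlp_b2 = numeric(d))
}

block_fwd <- function(x, p, heads) {
  d3 <- dim(x); N <- d3[1]; T <- d3[2]
  xm <- tokens_to_mat(x)
  ln1 <- layernorm_fwd(xm, p$ln1_g, p$ln1_b)
  att <- mha_fwd(mat_to_tokens(ln1$y, N, T), p$attn, heads)
  x1 <- xm + tokens_to_mat(att$y)
  ln2 <- layernorm_fwd(x1, p$ln2_g, p$ln2_b)
  h1 <- linear_fwd(ln2$y, p$mlp_W1, p$mlp_b1)
  h2 <- gelu_fwd(h1)
  h3 <- linear_fwd(h2, p$mlp_W2, p$mlp_b2)
  y <- x1 + h3
  list(y = mat_to_tokens(y, N, T),
       cache = list(ln1 = ln1, att = att, x1 = x1, ln2 = ln2, h1 = h1, h2 = h2,
                    N = N, T = T))
}

block_bwd <- function(cache, p, dy) {
  N <- cache$N; T <- cache$T
  dym <- tokens_to_mat(dy)
  g3 <- linear_bwd(cache$h2, p$mlp_W2, dym)
  dh1 <- gelu_bwd(cache$h1, g3$dx)
  g1 <- linear_bwd(cache$ln2$y, p$mlp_W1, dh1)
  l2 <- layernorm_bwd(cache$ln2, p$ln2_g, g1$dx)
  dx1 <- dym + l2$dx
  ga <- mha_bwd(cache$att$cache, p$attn, mat_to_tokens(dx1, N, T))
  l1 <- layernorm_bwd(cache$ln1, p$ln1_g, tokens_to_mat(ga$dx))
  dx <- dx1 + l1$dx
  list(dx = mat_to_tokens(dx, N, T),
       grads = list(ln1_g = l1$dg, ln1_b = l1$db, attn = ga$grads,
                    ln2_g = l2$dg, ln2_b = l2$db,
                    mlp_W1 = g1$dW, mlp_b1 = g1$db,
                    mlp_W2 = g3$dW, mlp_b2 = g3$db))
}

## ---- sinusoidal positional embeddings ------------------------------------

# 1D sin-cos table for a coordinate vector, dim d (even)
sincos_1d <- function(pos, d) {
  omega <- 1 / 10000^(seq_len(d / 2) / (d / 2))
  ang <- outer(pos, omega)
  cbind(sin(ang), cos(ang))
}

# fixed 2D sin-cos positional embedding for a gh x gw patch grid, dim d
posemb_2d <- function(gh, gw, d) {
  stopifnot(d %% 4 == 0)
  # patch order row-major: (r-1)*gw + c
  rr <- rep(seq_len(gh), each = gw) - 1
  cc <- rep(seq_len(gw), times = gh) - 1
  cbind(sincos_1d(rr, d / 2), sincos_1d(cc, d / 2))
}

## ---- conv feature maps ---------------------------------------------------

# feature map container: matrix (N*H*W) x C, pixel order sample-major then
# row-major: row = (n-1)*H*W + (r-1)*W + c
fmap <- function(mat, N, H, W) list(mat = mat, N = N, H = H, W = W)

image_batch_to_fmap <- function(images) {
  # images: array (N, H, W)
  d <- dim(images)
  m <- matrix(aperm(images, c(3, 2, 1)), d[2] * d[3] * d[1], 1)
  # aperm gives (W, H, N) column-major => index order W fastest, then H, then N:
  # flattening yields row-major pixels within sample, sample-major overall
  fmap(m, d[1], d[2], d[3])
}

fmap_to_image_batch <- function(fm, channel = 1L) {
  arr <- array(fm$mat[, channel], c(fm$W, fm$H, fm$N))
  aperm(arr, c(3, 2, 1))
}

conv_idx_cache <- new.env(parent = emptyenv())

# per-offset source row indices for 3x3 same-padding conv on an N x H x W grid;
# pad rows map to the sentinel N*H*W + 1
conv3_indices <- function(N, H, W) {
  key <- paste(N, H, W, sep = "x")
  got <- conv_idx_cache[[key]]
  if (!is.null(got)) return(got)
  rr <- rep(rep(seq_len(H), each = W), times = N)
  cc <- rep(rep(seq_len(W), times = H), times = N)
  nn <- rep(seq_len(N), each = H * W)
  sentinel <- N * H * W + 1L
  idx <- vector("list", 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    r2 <- rr + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    v <- (nn - 1L) * H * W + (r2 - 1L) * W + c2
    v[!ok] <- sentinel
    idx[[k]] <- v
  }
  conv_idx_cache[[key]] <- idx
  idx
}

im2col3 <- function(fm) {
  idx <- conv3_indices(fm$N, fm$H, fm$W)
  xaug <- rbind(fm$mat, 0)
  do.call(cbind, lapply(idx, function(v) xaug[v, , drop = FALSE]))
}

# W: (9*Cin) x Cout
conv3_fwd <- function(fm, W, b) {
  cols <- im2col3(fm)
  y <- linear_fwd(cols, W, b)
  list(out = fmap(y, fm$N, fm$H, fm$W), x = fm)
}

conv3_bwd <- function(cache, W, dy_mat) {
  fm <- cache$x
  cols <- im2col3(fm)                  # recomputed: cheaper than caching
  dW <- crossprod(cols, dy_mat)
  db <- colSums(dy_mat)
  dcols <- tcrossprod(dy_mat, W)
  idx <- conv3_indices(fm$N, fm$H, fm$W)
  Cin <- ncol(fm$mat)
  nr <- nrow(fm$mat)
  dx <- matrix(0, nr, Cin)
  for (k in seq_len(9L)) {
    v <- idx[[k]]
    keep <- v <= nr
    block <- dcols[keep, (k - 1L) * Cin + seq_len(Cin), drop = FALSE]
    tgt <- v[keep]
    dx[tgt, ] <- dx[tgt, ] + block
  }
  list(dW = dW, db = db, dx = dx)
}

pool_idx_cache <- new.env(parent = emptyenv())

pool2_indices <- function(N, H, W) {
  key <- paste(N, H, W, sep = "x")
  got <- pool_idx_cache[[key]]
  if (!is.null(got)) return(got)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  rr <- rep(rep(seq_len(H2), each = W2), times = N)
  cc <- rep(rep(seq_len(W2), times = H2), times = N)
  nn <- rep(seq_len(N), each = H2 * W2)
  base <- function(dr, dc) (nn - 1L) * H * W + (2L * rr - 2L + dr) * W + (2L * cc - 1L + dc)
  idx <- list(base(0L, 0L), base(0L, 1L), base(1L, 0L), base(1L, 1L))
  pool_idx_cache[[key]] <- idx
  idx
}

maxpool2_fwd <- function(fm) {
  idx <- pool2_indices(fm$N, fm$H, fm$W)
  a <- fm$mat[idx[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(a), ncol(a))
  y <- a
  for (k in 2:4) {
    b <- fm$mat[idx[[k]], , drop = FALSE]
    sel <- b > y
    y[sel] <- b[sel]
    arg[sel] <- k
  }
  list(out = fmap(y, fm$N, fm$H %/% 2L, fm$W %/% 2L),
       cache = list(idx = idx, arg = arg, nr = nrow(fm$mat)))
}

maxpool2_bwd <- function(cache, dy_mat) {
  dx <- matrix(0, cache$nr, ncol(dy_mat))
  for (k in 1:4) {
    sel <- cache$arg == k
    contrib <- dy_mat * sel
    v <- cache$idx[[k]]
    dx[v, ] <- dx[v, ] + contrib
  }
  dx
}

up_idx_cache <- new.env(parent = emptyenv())

upsample2_indices <- function(N, H, W) {
  key <- paste(N, H, W, sep = "x")
  got <- up_idx_cache[[key]]
  if (!is.null(got)) return(got)
  H2 <- 2L * H; W2 <- 2L * W
  rr <- rep(rep(seq_len(H2), each = W2), times = N)
  cc <- rep(rep(seq_len(W2), times = H2), times = N)
  nn <- rep(seq_len(N), each = H2 * W2)
  src <- (nn - 1L) * H * W + ((rr + 1L) %/% 2L - 1L) * W + (cc + 1L) %/% 2L
  up_idx_cache[[key]] <- src
  src
}

upsample2_fwd <- function(fm) {
  src <- upsample2_indices(fm$N, fm$H, fm$W)
  fmap(fm$mat[src, , drop = FALSE], fm$N, 2L * fm$H, 2L * fm$W)
}

upsample2_bwd <- function(N, H, W, dy_mat) {
  src <- upsample2_indices(N, H, W)
  dx <- rowsum(dy_mat, group = src)
  # all source rows are hit (every input pixel has 4 children), order sorted = identity
  dx
}

## ---- differentiable bilinear resize (as a sparse linear operator) --------

resize_mat_cache <- new.env(parent = emptyenv())

# sparse (Hout*Wout) x (Hin*Win) operator, row-major pixel order, center-aligned
bilinear_operator <- function(Hin, Win, Hout, Wout) {
  key <- paste(Hin, Win, Hout, Wout, sep = "x")
  got <- resize_mat_cache[[key]]
  if (!is.null(got)) return(got)
  axis_weights <- function(nin, nout) {
    pos <- (seq_len(nout) - 0.5) * nin / nout + 0.5
    lo <- floor(pos); w <- pos - lo
    lo <- pmin(pmax(lo, 1L), nin); hi <- pmin(lo + 1L, nin)
    w[hi == lo] <- 0
    list(lo = as.integer(lo), hi = as.integer(hi), w = w)
  }
  ar <- axis_weights(Hin, Hout); ac <- axis_weights(Win, Wout)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (cr in list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))) {
    ri <- if (cr[1] == 1) ar$lo else ar$hi
    wi <- if (cr[1] == 1) 1 - ar$w else ar$w
    cj <- if (cr[2] == 1) ac$lo else ac$hi
    wj <- if (cr[2] == 1) 1 - ac$w else ac$w
    rows <- c(rows, seq_len(Hout * Wout))
    cols <- c(cols, as.vector(t(outer((ri - 1L) * Win, cj, `+`))))
    vals <- c(vals, as.vector(t(outer(wi, wj))))
  }
  M <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(Hout * Wout, Hin * Win))
  resize_mat_cache[[key]] <- M
  M
}

# resize a batched feature map with the sparse operator (per sample)
fmap_resize_fwd <- function(fm, Hout, Wout) {
  M <- bilinear_operator(fm$H, fm$W, Hout, Wout)
  C <- ncol(fm$mat)
  out <- matrix(0, fm$N * Hout * Wout, C)
  for (n in seq_len(fm$N)) {
    src <- (n - 1L) * fm$H * fm$W + seq_len(fm$H * fm$W)
    dst <- (n - 1L) * Hout * Wout + seq_len(Hout * Wout)
    out[dst, ] <- as.matrix(M %*% fm$mat[src, , drop = FALSE])
  }
  fmap(out, fm$N, Hout, Wout)
}

fmap_resize_bwd <- function(N, Hin, Win, Hout, Wout, dy_mat) {
  M <- bilinear_operator(Hin, Win, Hout, Wout)
  C <- ncol(dy_mat)
  dx <- matrix(0, N * Hin * Win, C)
  for (n in seq_len(N)) {
    src <- (n - 1L) * Hin * Win + seq_len(Hin * Win)
    dst <- (n - 1L) * Hout * Wout + seq_len(Hout * Wout)
    dx[src, ] <- as.matrix(Matrix::crossprod(M, dy_mat[dst, , drop = FALSE]))
  }
  dx
}

## ---- AdamW ----------------------------------------------------------------

adamw_init <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 0.01) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(fp)) {
    g <- fg[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    fp[[nm]] <- fp[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * fp[[nm]])
  }
  list(params = relist_params(fp, params), state = state)
}

# elementwise sum of two congruent nested gradient lists
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (!is.list(a)) return(a + b)
  for (nm in names(a)) a[[nm]] <- grads_add(a[[nm]], b[[nm]])
  a
}

grads_scale <- function(a, s) {
  if (!is.list(a)) return(a * s)
  lapply(a, grads_scale, s = s)
}
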