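# Masked-autoencoder pretraining: ViT encoder over image patches, lightweight
# transformer decoder reconstructing only the masked patches, and a per-sample
# reconstruction loss weighted by brain coverage, so slices dominated by
# background or cropped fields of view pull less on the shared representation.

#' Vision-transformer / MAE configuration
#'
#' Two presets are bundled: `"tiny"` (64 px images, 8 px patches, 4 encoder
#' layers of width 64 — the desk-scale default used throughout the tests) and
#' `"vitbase"` (224 px images, 16 px patches, 12 encoder layers of width 768,
#' the configuration used at full scale). The decoder is deliberately
#' lightweight: masked-patch reconstruction needs far less capacity than
#' representation learning.
#'
#' @param preset `"tiny"` or `"vitbase"`, or `NULL` to pass all fields.
#' @param image_size,patch_size Input side length and patch side length
#'   (image_size must be divisible by patch_size).
#' @param encoder_layers,encoder_dim,heads Encoder depth E, width d, heads.
#' @param decoder_layers,decoder_dim,decoder_heads Decoder depth D and width.
#' @param in_channels Input channels (1 for grayscale MRI).
#' @param mask_ratio Fraction of patches masked during pretraining.
#' @return A `vit_config` list (includes the derived patch grid).
#' @export
vit_config <- function(preset = c("tiny", "vitbase"), image_size = NULL,
                       patch_size = NULL, encoder_layers = NULL,
                       encoder_dim = NULL, heads = NULL, decoder_layers = NULL,
                       decoder_dim = NULL, decoder_heads = NULL,
                       in_channels = 1L, mask_ratio = 0.75) {
  defaults <- switch(match.arg(preset),
    tiny = list(image_size = 64L, patch_size = 8L, encoder_layers = 4L,
                encoder_dim = 64L, heads = 4L, decoder_layers = 2L,
                decoder_dim = 64L, decoder_heads = 4L),
    vitbase = list(image_size = 224L, patch_size = 16L, encoder_layers = 12L,
                   encoder_dim = 768L, heads = 12L, decoder_layers = 8L,
                   decoder_dim = 512L, decoder_heads = 16L))
  cfg <- list(image_size = image_size %||% defaults$image_size,
              patch_size = patch_size %||% defaults$patch_size,
              encoder_layers = encoder_layers %||% defaults$encoder_layers,
              encoder_dim = encoder_dim %||% defaults$encoder_dim,
              heads = heads %||% defaults$heads,
              decoder_layers = decoder_layers %||% defaults$decoder_layers,
              decoder_dim = decoder_dim %||% defaults$decoder_dim,
              decoder_heads = decoder_heads %||% defaults$decoder_heads,
              in_channels = as.integer(in_channels), mask_ratio = mask_ratio,
              preset = match.arg(preset))
  stop_if(cfg$image_size %% cfg$patch_size != 0,
          "`image_size` must be divisible by `patch_size`.")
  stop_if(cfg$encoder_dim %% cfg$heads != 0, "`encoder_dim` must be divisible by `heads`.")
  cfg$grid <- cfg$image_size %/% cfg$patch_size
  cfg$n_patches <- cfg$grid^2
  class(cfg) <- "vit_config"
  cfg
}

#' Split an image into non-overlapping patches
#'
#' Patches are ordered row-major over the patch grid; pixels within a patch are
#' row-major too. `unpatchify(patchify(x), ...)` is bit-exact.
#'
#' @param image 2D array with sides divisible by `patch_size`.
#' @param patch_size Patch side length.
#' @return Matrix of `n_patches` rows and `patch_size^2` columns.
#' @export
patchify <- function(image, patch_size) {
  d <- dim(image)
  stop_if(is.null(d) || length(d) != 2, "`image` must be 2D.")
  stop_if(any(d %% patch_size != 0), "image sides must be divisible by `patch_size`.")
  idx <- patch_index(d[1], d[2], patch_size)
  matrix(image[idx], nrow = nrow(idx), ncol = ncol(idx))
}

#' Reassemble an image from patches
#'
#' @param patches Matrix from [patchify()].
#' @param image_size Output side length (square image).
#' @param patch_size Patch side length.
#' @return 2D array.
#' @export
unpatchify <- function(patches, image_size, patch_size) {
  idx <- patch_index(image_size, image_size, patch_size)
  stop_if(!all(dim(patches) == dim(idx)), "patch matrix has the wrong shape.")
  out <- matrix(0, image_size, image_size)
  out[idx] <- patches
  out
}

patch_idx_cache <- new.env(parent = emptyenv())

patch_index <- function(H, W, p) {
  key <- paste(H, W, p, sep = "x")
  got <- patch_idx_cache[[key]]
  if (!is.null(got)) return(got)
  gh <- H %/% p; gw <- W %/% p
  idx <- matrix(0L, gh * gw, p * p)
  for (rp in seq_len(gh)) for (cp in seq_len(gw)) {
    q <- (rp - 1L) * gw + cp
    k <- 0L
    v <- integer(p * p)
    for (a in seq_len(p)) for (b in seq_len(p)) {
      k <- k + 1L
      v[k] <- (rp - 1L) * p + a + ((cp - 1L) * p + b - 1L) * H
    }
    idx[q, ] <- v
  }
  patch_idx_cache[[key]] <- idx
  idx
}

#' Random patch-masking plan
#'
#' Selects `round(mask_ratio * n_patches)` patches uniformly without
#' replacement; masked and kept indices partition the patch set. Deterministic
#' per seed.
#'
#' @param n_patches Total number of patches.
#' @param mask_ratio Fraction to mask, strictly between 0 and 1.
#' @param seed RNG seed.
#' @return A `mask_plan`: list with 0-based `masked` and `kept` index vectors
#'   and the seed.
#' @export
random_mask <- function(n_patches, mask_ratio, seed) {
  stop_if(!is.numeric(mask_ratio) || mask_ratio <= 0 || mask_ratio >= 1,
          "`mask_ratio` must lie strictly between 0 and 1.")
  set.seed(seed)
  n_mask <- round(mask_ratio * n_patches)
  masked <- sort(sample.int(n_patches, n_mask)) - 1L
  structure(list(masked = masked,
                 kept = setdiff(seq_len(n_patches) - 1L, masked),
                 seed = as.integer(seed)),
            class = "mask_plan")
}

#' Coverage-to-weight mapping
#'
#' Monotone increasing map from brain coverage to the per-sample loss weight:
#' `w = w_min + (1 - w_min) * alpha`, so empty slices keep a small floor weight
#' and full-coverage slices weigh 1.
#'
#' @param alpha Coverage fraction(s) in `[0, 1]`.
#' @param w_min Weight floor at zero coverage (default 0.1).
#' @return Weight(s) in `[w_min, 1]`.
#' @export
coverage_weight <- function(alpha, w_min = 0.1) {
  stop_if(any(alpha < 0 | alpha > 1), "`alpha` must lie in [0, 1].")
  w_min + (1 - w_min) * alpha
}

#' Per-sample masked-patch reconstruction error
#'
#' Mean over *masked* patches of the per-patch mean squared error; kept patches
#' contribute nothing.
#'
#' @param reconstruction,target Patch matrices (`n_patches` x `patch_size^2`).
#' @param plan A `mask_plan`.
#' @return Scalar loss.
#' @export
per_sample_masked_mse <- function(reconstruction, target, plan) {
  stop_if(!all(dim(reconstruction) == dim(target)), "shape mismatch.")
  stop_if(length(plan$masked) == 0L, "empty masked set.")
  rows <- plan$masked + 1L
  diff <- reconstruction[rows, , drop = FALSE] - target[rows, , drop = FALSE]
  mean(rowMeans(diff^2))
}

#' Coverage-weighted batch loss
#'
#' `L = (1/N) * sum_i w_i * l_i` over per-sample masked reconstruction losses;
#' with uniform unit weights this reduces to the plain mean (the original MAE
#' objective). There is no renormalization by the weight sum.
#'
#' @param l_tilde Per-sample losses.
#' @param w Per-sample weights (default 1).
#' @return Scalar batch loss.
#' @export
weighted_batch_loss <- function(l_tilde, w = rep(1, length(l_tilde))) {
  stop_if(length(l_tilde) == 0L, "empty batch.")
  stop_if(length(w) != length(l_tilde), "`w` and `l_tilde` lengths differ.")
  mean(w * l_tilde)
}

## ---- model --------------------------------------------------------------

mae_init <- function(config, seed = 1L) {
  set.seed(seed)
  d <- config$encoder_dim
  pp <- config$patch_size^2 * config$in_channels
  params <- list(
    patch_W = xavier_init(pp, d), patch_b = numeric(d),
    cls = matrix(rnorm(d, 0, 0.02), 1, d),
    enc = lapply(seq_len(config$encoder_layers), function(i) block_init(d)),
    enc_ln_g = rep(1, d), enc_ln_b = numeric(d),
    dec_W = xavier_init(d, config$decoder_dim), dec_b = numeric(config$decoder_dim),
    mask_token = matrix(rnorm(config$decoder_dim, 0, 0.02), 1, config$decoder_dim),
    dec = lapply(seq_len(config$decoder_layers), function(i) block_init(config$decoder_dim)),
    dec_ln_g = rep(1, config$decoder_dim), dec_ln_b = numeric(config$decoder_dim),
    head_W = xavier_init(config$decoder_dim, pp), head_b = numeric(pp)
  )
  names(params$enc) <- paste0("L", seq_along(params$enc))
  names(params$dec) <- paste0("L", seq_along(params$dec))
  params
}

mae_pos <- function(config) {
  list(enc = posemb_2d(config$grid, config$grid, config$encoder_dim),
       dec = posemb_2d(config$grid, config$grid, config$decoder_dim))
}

# stack images (list of 2D arrays or N x H x W array) into patch tokens
stack_patches <- function(images, config) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3) {
    images <- lapply(seq_len(dim(images)[1]), function(i) images[i, , ])
  }
  N <- length(images)
  P <- config$n_patches; pp <- config$patch_size^2
  out <- array(0, c(N, P, pp))
  for (n in seq_len(N)) {
    stop_if(!all(dim(images[[n]]) == config$image_size),
            "image size does not match the model configuration.")
    out[n, , ] <- patchify(images[[n]], config$patch_size)
  }
  out
}

# full (unmasked) encoder forward; returns CLS embedding, per-layer states and
# block caches (when requested for training the decoder path is not needed)
encoder_forward <- function(params, config, images, keep = NULL, want_cache = FALSE) {
  patches <- stack_patches(images, config)
  N <- dim(patches)[1]; P <- dim(patches)[2]
  pos <- mae_pos(config)$enc
  pm <- tokens_to_mat(patches)
  emb <- linear_fwd(pm, params$patch_W, params$patch_b)
  emb <- mat_to_tokens(emb, N, P)
  # add positional embedding (same table for every sample)
  emb <- emb + aperm(array(rep(t(pos), N), c(config$encoder_dim, P, N)), c(3, 2, 1))
  if (!is.null(keep)) emb <- emb[, keep, , drop = FALSE]
  Tn <- dim(emb)[2] + 1L
  x <- array(0, c(N, Tn, config$encoder_dim))
  x[, 1, ] <- matrix(rep(params$cls, each = N), N, config$encoder_dim)
  x[, 2:Tn, ] <- emb
  states <- vector("list", config$encoder_layers)
  caches <- if (want_cache) vector("list", config$encoder_layers)
  for (i in seq_len(config$encoder_layers)) {
    bf <- block_fwd(x, params$enc[[i]], config$heads)
    x <- bf$y
    states[[i]] <- x
    if (want_cache) caches[[i]] <- bf$cache
  }
  xm <- tokens_to_mat(x)
  ln <- layernorm_fwd(xm, params$enc_ln_g, params$enc_ln_b)
  final <- mat_to_tokens(ln$y, N, Tn)
  list(final = final, states = states, caches = caches, ln = ln,
       patches = patches, N = N, T = Tn)
}

#' Encode a batch of slices into token sequences
#'
#' Runs the full (unmasked) encoder and returns the final-layer tokens (CLS at
#' position 1, after the final layer norm) together with every intermediate
#' layer state — the representation tapped by the fusion segmenter.
#'
#' @param checkpoint An `mae_checkpoint` (see [mae_pretrain()]).
#' @param images List of 2D arrays, or an `N x H x W` array, matching the
#'   configured image size.
#' @return A `token_sequence`: list with `tokens` (N, n_patches+1, d) final
#'   states, `per_layer_states` (list of E arrays, CLS included at position 1),
#'   and `patch_grid`.
#' @export
encode_tokens <- function(checkpoint, images) {
  stop_if(!inherits(checkpoint, "mae_checkpoint"), "`checkpoint` must be an mae_checkpoint.")
  config <- checkpoint$config
  ef <- encoder_forward(checkpoint$params, config, images)
  structure(list(tokens = ef$final, per_layer_states = ef$states,
                 patch_grid = c(config$grid, config$grid)),
            class = "token_sequence")
}

## ---- masked forward/backward for pretraining ------------------------------

mae_forward <- function(params, config, images, plans, alphas, w_min = 0.1) {
  patches <- stack_patches(images, config)
  N <- dim(patches)[1]; P <- dim(patches)[2]; pp <- dim(patches)[3]
  d <- config$encoder_dim; dd <- config$decoder_dim
  pos <- mae_pos(config)
  n_keep <- length(plans[[1]]$kept)
  # embed kept patches (per-sample kept sets differ, so gather per sample)
  kept_tok <- array(0, c(N, n_keep, pp))
  for (n in seq_len(N)) kept_tok[n, , ] <- patches[n, plans[[n]]$kept + 1L, ]
  km <- tokens_to_mat(kept_tok)
  emb <- linear_fwd(km, params$patch_W, params$patch_b)
  emb <- mat_to_tokens(emb, N, n_keep)
  for (n in seq_len(N)) emb[n, , ] <- emb[n, , ] + pos$enc[plans[[n]]$kept + 1L, ]
  Tn <- n_keep + 1L
  x <- array(0, c(N, Tn, d))
  x[, 1, ] <- matrix(rep(params$cls, each = N), N, d)
  x[, 2:Tn, ] <- emb
  enc_caches <- vector("list", config$encoder_layers)
  for (i in seq_len(config$encoder_layers)) {
    bf <- block_fwd(x, params$enc[[i]], config$heads)
    x <- bf$y; enc_caches[[i]] <- bf$cache
  }
  xm <- tokens_to_mat(x)
  enc_ln <- layernorm_fwd(xm, params$enc_ln_g, params$enc_ln_b)
  # decoder: embed kept tokens (CLS dropped), insert mask tokens, add dec pos
  enc_out <- mat_to_tokens(enc_ln$y, N, Tn)
  kept_only <- enc_out[, 2:Tn, , drop = FALSE]
  km2 <- tokens_to_mat(kept_only)
  dec_emb <- linear_fwd(km2, params$dec_W, params$dec_b)
  dec_emb <- mat_to_tokens(dec_emb, N, n_keep)
  z <- array(rep(params$mask_token, each = N * P), c(N, P, dd))
  for (n in seq_len(N)) z[n, plans[[n]]$kept + 1L, ] <- dec_emb[n, , ]
  z <- z + aperm(array(rep(t(pos$dec), N), c(dd, P, N)), c(3, 2, 1))
  dec_caches <- vector("list", config$decoder_layers)
  for (i in seq_len(config$decoder_layers)) {
    bf <- block_fwd(z, params$dec[[i]], config$decoder_heads)
    z <- bf$y; dec_caches[[i]] <- bf$cache
  }
  zm <- tokens_to_mat(z)
  dec_ln <- layernorm_fwd(zm, params$dec_ln_g, params$dec_ln_b)
  pred <- linear_fwd(dec_ln$y, params$head_W, params$head_b)  # (N*P) x pp
  pred_tok <- mat_to_tokens(pred, N, P)
  l_tilde <- numeric(N)
  for (n in seq_len(N)) {
    l_tilde[n] <- per_sample_masked_mse(pred_tok[n, , ], patches[n, , ], plans[[n]])
  }
  w <- coverage_weight(alphas, w_min)
  list(loss = weighted_batch_loss(l_tilde, w), l_tilde = l_tilde, w = w,
       cache = list(patches = patches, plans = plans, pred_tok = pred_tok,
                    enc_caches = enc_caches, dec_caches = dec_caches,
                    enc_ln = enc_ln, dec_ln = dec_ln, dec_lnx = zm,
                    km = km, km2 = km2, N = N, P = P, Tn = Tn,
                    n_keep = n_keep, pp = pp, d = d, dd = dd))
}

mae_backward <- function(params, config, fw) {
  ch <- fw$cache
  N <- ch$N; P <- ch$P; Tn <- ch$Tn; n_keep <- ch$n_keep
  pp <- ch$pp; d <- ch$d; dd <- ch$dd
  # dL/dpred on masked patches: w_n / (N * n_masked * pp) * 2 * (pred - target)
  dpred <- array(0, c(N, P, pp))
  for (n in seq_len(N)) {
    rows <- ch$plans[[n]]$masked + 1L
    nm <- length(rows)
    dpred[n, rows, ] <- (2 * fw$w[n] / (N * nm * pp)) *
      (ch$pred_tok[n, rows, ] - ch$patches[n, rows, ])
  }
  dpm <- tokens_to_mat(dpred)
  gh <- linear_bwd(ch$dec_ln$y, params$head_W, dpm)
  gl <- layernorm_bwd(ch$dec_ln, params$dec_ln_g, gh$dx)
  dz <- mat_to_tokens(gl$dx, N, P)
  grads <- list(head_W = gh$dW, head_b = gh$db,
                dec_ln_g = gl$dg, dec_ln_b = gl$db)
  gdec <- vector("list", config$decoder_layers)
  for (i in rev(seq_len(config$decoder_layers))) {
    bb <- block_bwd(ch$dec_caches[[i]], params$dec[[i]], dz)
    dz <- bb$dx; gdec[[i]] <- bb$grads
  }
  names(gdec) <- paste0("L", seq_along(gdec))
  grads$dec <- gdec
  # split dz into mask-token grad and kept-token grads (dec pos is fixed)
  dmask <- matrix(0, 1, dd)
  dkept <- array(0, c(N, n_keep, dd))
  for (n in seq_len(N)) {
    kept1 <- ch$plans[[n]]$kept + 1L
    masked1 <- ch$plans[[n]]$masked + 1L
    dkept[n, , ] <- dz[n, kept1, ]
    dmask <- dmask + colSums(matrix(dz[n, masked1, ], length(masked1), dd))
  }
  grads$mask_token <- dmask
  gde <- linear_bwd(ch$km2, params$dec_W, tokens_to_mat(dkept))
  grads$dec_W <- gde$dW; grads$dec_b <- gde$db
  # back into encoder output: kept tokens get gradient, CLS gets zero from decoder
  denc_out <- array(0, c(N, Tn, d))
  denc_out[, 2:Tn, ] <- mat_to_tokens(gde$dx, N, n_keep)
  gel <- layernorm_bwd(ch$enc_ln, params$enc_ln_g, tokens_to_mat(denc_out))
  grads$enc_ln_g <- gel$dg; grads$enc_ln_b <- gel$db
  dx <- mat_to_tokens(gel$dx, N, Tn)
  genc <- vector("list", config$encoder_layers)
  for (i in rev(seq_len(config$encoder_layers))) {
    bb <- block_bwd(ch$enc_caches[[i]], params$enc[[i]], dx)
    dx <- bb$dx; genc[[i]] <- bb$grads
  }
  names(genc) <- paste0("L", seq_along(genc))
  grads$enc <- genc
  grads$cls <- matrix(colSums(matrix(dx[, 1, ], N, d)), 1, d)
  demb <- dx[, 2:Tn, , drop = FALSE]
  gpe <- linear_bwd(ch$km, params$patch_W, tokens_to_mat(demb))
  grads$patch_W <- gpe$dW; grads$patch_b <- gpe$db
  grads
}

## ---- pretraining loop ------------------------------------------------------

#' MAE pretraining on a slice dataset
#'
#' Trains the masked autoencoder with AdamW on preprocessed slices, weighting
#' each sample's masked-patch reconstruction error by its brain coverage.
#' Deterministic given `seed`; a run can be resumed from a checkpoint and
#' reproduces the interrupted trajectory.
#'
#' @param dataset A list with `images` (list of 2D arrays in `[0,1]`) and
#'   `alpha` (coverage fractions, same length). See [as_slice_dataset()].
#' @param config A [vit_config()].
#' @param epochs Training epochs.
#' @param batch_size Batch size (default 48, truncated to the dataset size).
#' @param lr AdamW learning rate (default 1e-4).
#' @param weight_decay AdamW weight decay.
#' @param w_min Coverage-weight floor (see [coverage_weight()]).
#' @param augment Apply seeded rotation/flip/crop augmentation to each slice
#'   every epoch (coverage recomputed from the augmented mask)? Default `TRUE`.
#' @param seed Master RNG seed for initialization, masking, augmentation and
#'   shuffling.
#' @param resume_from Optional `mae_checkpoint` to continue from.
#' @param verbose Print per-epoch loss?
#' @return An `mae_checkpoint`: list with `params`, `config`, `seed`, `epoch`,
#'   `loss_curve` (tibble epoch/loss), and `optimizer` state.
#' @export
mae_pretrain <- function(dataset, config, epochs = 10, batch_size = 48,
                         lr = 1e-4, weight_decay = 0.01, w_min = 0.1,
                         augment = TRUE, seed = 1L, resume_from = NULL,
                         verbose = FALSE) {
  stop_if(length(dataset$images) == 0L, "empty dataset.")
  stop_if(!all(dim(dataset$images[[1]]) == config$image_size),
          "dataset image size does not match `config`.")
  n <- length(dataset$images)
  alphas <- dataset$alpha %||% rep(1, n)
  batch_size <- min(batch_size, n)
  if (is.null(resume_from)) {
    params <- mae_init(config, seed = derive_seed(seed, "mae-init"))
    opt <- adamw_init(params)
    epoch0 <- 0L
    loss_curve <- tibble::tibble(epoch = integer(0), loss = numeric(0))
  } else {
    params <- resume_from$params
    opt <- resume_from$optimizer
    epoch0 <- resume_from$epoch
    loss_curve <- resume_from$loss_curve
  }
  for (ep in (epoch0 + 1L):(epoch0 + epochs)) {
    set.seed(derive_seed(seed, "mae-shuffle", ep))
    ord <- sample.int(n)
    ep_loss <- 0; n_batches <- 0L
    for (b0 in seq(1L, n, by = batch_size)) {
      ids <- ord[b0:min(b0 + batch_size - 1L, n)]
      plans <- lapply(seq_along(ids), function(j) {
        random_mask(config$n_patches, config$mask_ratio,
                    derive_seed(seed, "mae-mask", ep * 1000L + ids[j]))
      })
      imgs <- dataset$images[ids]
      a_b <- alphas[ids]
      if (augment) {
        for (j in seq_along(ids)) {
          s <- slice_sample_new(imgs[[j]],
                                brain_mask = dataset$brain_masks[[ids[j]]],
                                alpha = a_b[j])
          s <- augment_slice(s, seed = derive_seed(seed, "mae-aug",
                                                   ep * 100000L + ids[j]))
          imgs[[j]] <- s$image
          if (!is.null(s$brain_mask)) a_b[j] <- brain_coverage(s$brain_mask)
        }
      }
      fw <- mae_forward(params, config, imgs, plans, a_b, w_min = w_min)
      gr <- mae_backward(params, config, fw)
      st <- adamw_step(params, gr, opt, lr = lr, weight_decay = weight_decay)
      params <- st$params; opt <- st$state
      ep_loss <- ep_loss + fw$loss; n_batches <- n_batches + 1L
    }
    loss_curve <- dplyr::bind_rows(loss_curve,
                                   tibble::tibble(epoch = ep, loss = ep_loss / n_batches))
    if (verbose) message(sprintf("epoch %d: loss %.6f", ep, ep_loss / n_batches))
  }
  structure(list(params = params, config = config, seed = seed,
                 epoch = epoch0 + epochs, loss_curve = loss_curve,
                 optimizer = opt),
            class = "mae_checkpoint")
}

#' Bundle slice samples into an in-memory training dataset
#'
#' @param samples List of `slice_sample`s (see [slice_sample_new()]).
#' @param size Resize slices to this side length (default: leave unchanged).
#' @return List with `images`, `alpha`, `labels` (label maps where present),
#'   `sequence_label`, usable by the training functions.
#' @export
as_slice_dataset <- function(samples, size = NULL) {
  imgs <- vector("list", length(samples))
  labels <- vector("list", length(samples))
  bmasks <- vector("list", length(samples))
  alpha <- numeric(length(samples))
  seq_label <- integer(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    img <- s$image; lab <- s$labels; bm <- s$brain_mask
    if (!is.null(size) && !all(dim(img) == size)) {
      rs <- resize_to_input(img, mask = lab, size = size)
      img <- rs$image; lab <- rs$mask
      if (!is.null(bm)) bm <- resize_to_input(bm * 1, size = size)$image > 0.5
    }
    alpha[i] <- if (!is.null(bm)) brain_coverage(bm) else s$alpha %||% NA_real_
    img[img < 0] <- 0; img[img > 1] <- 1
    imgs[[i]] <- img
    labels[[i]] <- lab
    bmasks[[i]] <- bm
    seq_label[i] <- s$sequence_label %||% NA_integer_
  }
  alpha[is.na(alpha)] <- 1
  list(images = imgs, alpha = alpha, labels = labels, brain_masks = bmasks,
       sequence_label = seq_label)
}

#' Save / load an MAE checkpoint
#'
#' Weights are serialized to an RDS file with a JSON sidecar recording the
#' configuration, seed, epoch and loss curve.
#'
#' @param checkpoint An `mae_checkpoint`.
#' @param path Path of the weights file (sidecar gets `.json` appended).
#' @return `path`, invisibly (`save_checkpoint`); the checkpoint
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  sidecar <- list(config = unclass(checkpoint$config), seed = checkpoint$seed,
                  epoch = checkpoint$epoch,
                  loss_curve = as.list(checkpoint$loss_curve),
                  params_hash = param_hash(checkpoint$params))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
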