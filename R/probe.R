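# Frozen-encoder linear probing: the final-layer CLS embedding of each slice
# feeds a C x d linear classifier trained with cross-entropy; the encoder is
# never updated, so the trainable parameter count is C * (d + 1).

#' CLS embedding of one or more slices
#'
#' Final-encoder-layer CLS token (after the final layer norm), computed with no
#' masking; the encoder weights are read-only.
#'
#' @param checkpoint An `mae_checkpoint`.
#' @param images A single 2D array, a list of them, or an `N x H x W` array.
#' @return Matrix `N x d` of embeddings.
#' @export
extract_cls <- function(checkpoint, images) {
  if (is.matrix(images) && length(dim(images)) == 2) images <- list(images)
  ts <- encode_tokens(checkpoint, images)
  emb <- ts$tokens[, 1, , drop = FALSE]
  matrix(emb, dim(ts$tokens)[1], dim(ts$tokens)[3])
}

#' Multi-class cross-entropy from raw logits
#'
#' `-z_y + log(sum_j exp(z_j))`, evaluated with log-sum-exp stabilization so it
#' is invariant to adding a constant to all logits.
#'
#' @param logits Numeric vector (one sample) or matrix (rows = samples).
#' @param label 0-based class index (vector for matrix input).
#' @return Mean loss over samples.
#' @export
cross_entropy <- function(logits, label) {
  if (is.null(dim(logits))) logits <- matrix(logits, 1)
  stop_if(any(!is.finite(logits)), "logits must be finite.")
  label <- as.integer(label)
  C <- ncol(logits)
  stop_if(any(label < 0L | label >= C), "label out of range.")
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  zy <- logits[cbind(seq_len(nrow(logits)), label + 1L)]
  mean(lse - zy)
}

#' Train a linear probe on frozen CLS embeddings
#'
#' Embeddings are computed once through the frozen encoder, then only the
#' `C x d` weight matrix and `C` biases are optimized with full-batch AdamW on
#' the cross-entropy loss. Deterministic under a fixed seed.
#'
#' @param dataset Slice dataset from [as_slice_dataset()] with `sequence_label`
#'   set, or a list with precomputed `embeddings` (N x d) and `labels`.
#' @param checkpoint Frozen `mae_checkpoint` (ignored when embeddings are
#'   supplied).
#' @param n_classes Number of classes C.
#' @param class_names Optional class names (length C).
#' @param epochs Full-batch AdamW steps.
#' @param lr Learning rate (default 1e-4).
#' @param augment Expand the training slices with seeded augmented views before
#'   embedding (default `TRUE`; evaluation is never augmented)?
#' @param n_views Total views per slice when augmenting (original included).
#' @param standardize Z-score the embeddings with training-set statistics
#'   before fitting (stored in the head and re-applied at prediction)?
#' @param seed RNG seed for head initialization and augmentation.
#' @param verbose Print progress?
#' @return A `probe_head`: list with `W` (C x d), `b`, `class_names`,
#'   `n_trainable`, `training_log` tibble, and the encoder hash it was trained
#'   against.
#' @export
train_probe <- function(dataset, checkpoint = NULL, n_classes,
                        class_names = NULL, epochs = 200, lr = 1e-4,
                        augment = TRUE, n_views = 16, standardize = TRUE,
                        seed = 1L, verbose = FALSE) {
  if (!is.null(dataset$embeddings)) {
    X <- dataset$embeddings
    y <- as.integer(dataset$labels)
    enc_hash <- NA_character_
  } else {
    stop_if(is.null(checkpoint), "`checkpoint` required unless embeddings are supplied.")
    stop_if(length(dataset$images) == 0L, "empty training manifest.")
    imgs <- dataset$images
    y <- as.integer(dataset$sequence_label)
    if (augment && n_views > 1) {
      n0 <- length(imgs)
      for (i in seq_len(n0)) {
        s <- slice_sample_new(imgs[[i]],
                              brain_mask = dataset$brain_masks[[i]] %||% NULL,
                              sequence_label = y[i])
        for (v in seq_len(n_views - 1L)) {
          a <- augment_slice(s, seed = derive_seed(seed, "probe-aug", i * 100L + v))
          imgs[[length(imgs) + 1L]] <- a$image
          y <- c(y, y[i])
        }
      }
    }
    X <- extract_cls(checkpoint, imgs)
    enc_hash <- param_hash(checkpoint$params)
  }
  stop_if(anyNA(y), "missing sequence labels.")
  if (standardize) {
    center <- colMeans(X)
    # population sd: invariant under duplicating the training set
    scale <- sqrt(colMeans(sweep(X, 2, center)^2))
    scale[scale < 1e-8] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale, `/`)
  } else {
    center <- NULL; scale <- NULL
  }
  present <- sort(unique(y))
  if (length(present) < n_classes) {
    rlang::warn(sprintf("classes absent from training data: %s",
                        paste(setdiff(0:(n_classes - 1), present), collapse = ", ")))
  }
  d <- ncol(X); N <- nrow(X)
  set.seed(seed)
  W <- matrix(rnorm(n_classes * d, 0, 0.01), n_classes, d)
  b <- numeric(n_classes)
  params <- list(W = W, b = b)
  opt <- adamw_init(params)
  onehot <- matrix(0, N, n_classes)
  onehot[cbind(seq_len(N), y + 1L)] <- 1
  log_rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    z <- tcrossprod(X, params$W)
    z <- sweep(z, 2, params$b, `+`)
    p <- softmax_rows(z)
    loss <- cross_entropy(z, y)
    dz <- (p - onehot) / N
    gr <- list(W = crossprod(dz, X), b = colSums(dz))
    st <- adamw_step(params, gr, opt, lr = lr, weight_decay = 0)
    params <- st$params; opt <- st$state
    log_rows[[ep]] <- tibble::tibble(epoch = ep, loss = loss)
    if (verbose && ep %% 50 == 0) message(sprintf("probe epoch %d: %.5f", ep, loss))
  }
  structure(list(W = params$W, b = params$b, center = center, scale = scale,
                 class_names = class_names %||% paste0("class", 0:(n_classes - 1)),
                 n_trainable = n_classes * (d + 1L),
                 training_log = dplyr::bind_rows(log_rows),
                 encoder_hash = enc_hash),
            class = "probe_head")
}

#' Predict sequence labels from embeddings
#'
#' Softmax probabilities over classes; the predicted label is the argmax with
#' ties broken toward the lowest class index.
#'
#' @param head A `probe_head`.
#' @param embeddings Matrix `N x d` (e.g. from [extract_cls()]).
#' @return Tibble with `label` (0-based), `class_name`, and one probability
#'   column per class (`p_<name>`).
#' @export
predict_probe <- function(head, embeddings) {
  stop_if(ncol(embeddings) != ncol(head$W), "embedding dimension mismatch.")
  if (!is.null(head$center)) {
    embeddings <- sweep(sweep(embeddings, 2, head$center), 2, head$scale, `/`)
  }
  z <- tcrossprod(embeddings, head$W)
  z <- sweep(z, 2, head$b, `+`)
  p <- softmax_rows(z)
  lab <- max.col(p, ties.method = "first") - 1L
  out <- tibble::tibble(label = lab, class_name = head$class_names[lab + 1L])
  probs <- tibble::as_tibble(as.data.frame(p))
  names(probs) <- paste0("p_", head$class_names)
  dplyr::bind_cols(out, probs)
}

#' @export
tidy.probe_head <- function(x, ...) x$training_log

#' @export
glance.probe_head <- function(x, ...) {
  tibble::tibble(n_classes = nrow(x$W), dim = ncol(x$W),
                 n_trainable = x$n_trainable,
                 final_loss = utils::tail(x$training_log$loss, 1))
}
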