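#' @importFrom rlang abort warn hash %||%
#' @importFrom stats rnorm runif quantile sd
#' @importFrom utils head tail
NULL

`%||%` <- rlang::`%||%`

stop_if <- function(cond, msg, class = "maefunet_error") {
  if (isTRUE(cond)) rlang::abort(msg, class = class)
  invisible(NULL)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

#' Derive a per-stage seed from a master seed
#'
#' Experiment stages (phantom generation, pretraining, probing, segmentation,
#' sweeps) each receive their own RNG seed derived deterministically from a
#' single master seed and a stage label, so stages are reproducible in
#' isolation and independent of one another.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage label (e.g. `"pretrain"`).
#' @param index Optional integer counter for repeated stages (sweep runs).
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, stage, index = 0L) {
  stop_if(!is.numeric(master_seed) || length(master_seed) != 1L,
          "`master_seed` must be a single integer.")
  key <- paste0(format(master_seed, scientific = FALSE), "/", stage, "/", index)
  # fold the utf8 bytes of the key into a 31-bit integer (deterministic, R-version stable)
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

param_count <- function(params) {
  sum(vapply(params, length, numeric(1)))
}

#' Content hash of a parameter list
#'
#' Used to assert the frozen-encoder contract: the hash of the encoder weights
#' must be identical before and after probe or segmenter training.
#'
#' @param params A (possibly nested) list of numeric arrays.
#' @return A character hash.
#' @export
param_hash <- function(params) {
  rlang::hash(params)
}

flatten_params <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    x <- params[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x)) out <- c(out, flatten_params(x, key)) else out[[key]] <- x
  }
  out
}

relist_params <- function(flat, skeleton, prefix = "") {
  for (nm in names(skeleton)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(skeleton[[nm]])) {
      skeleton[[nm]] <- relist_params(flat, skeleton[[nm]], key)
    } else {
      skeleton[[nm]] <- flat[[key]]
    }
  }
  skeleton
}
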