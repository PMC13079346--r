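# Classification and segmentation evaluation: one-vs-rest confusion counts,
# accuracy/precision/recall and the micro/macro/weighted F1 variants, Dice and
# IoU overlap scores, and mean/population-std stability summaries.

#' One-vs-rest confusion counts for multi-class labels
#'
#' Builds the K x K confusion matrix and derives per-class one-vs-rest counts
#' (TP, FP, FN, TN) together with per-class ground-truth totals.
#'
#' @param truth Integer vector of ground-truth class labels in `[0, K)`.
#' @param pred Integer vector of predicted labels, same length.
#' @param n_classes Number of classes `K`.
#' @return An object of class `confusion_counts`: list with `K`, `matrix`
#'   (rows = predicted, columns = truth), and a tibble `counts` with columns
#'   `class`, `tp`, `fp`, `fn`, `tn`, `n_true`.
#' @export
confusion_counts <- function(truth, pred, n_classes) {
  stop_if(length(truth) != length(pred), "`truth` and `pred` must have equal length.")
  stop_if(length(truth) == 0L, "empty label vectors.")
  stop_if(!is_count(n_classes, min = 1), "`n_classes` must be a positive integer.")
  truth <- as.integer(truth); pred <- as.integer(pred)
  stop_if(any(truth < 0L | truth >= n_classes | pred < 0L | pred >= n_classes),
          "labels must lie in [0, n_classes).")
  K <- as.integer(n_classes)
  m <- matrix(0L, K, K, dimnames = list(pred = 0:(K - 1), truth = 0:(K - 1)))
  tab <- table(factor(pred, levels = 0:(K - 1)), factor(truth, levels = 0:(K - 1)))
  m[] <- as.integer(tab)
  tp <- diag(m)
  fp <- rowSums(m) - tp   # predicted k but truth != k
  fn <- colSums(m) - tp   # truth k but predicted != k
  n <- length(truth)
  tn <- n - tp - fp - fn
  out <- list(
    K = K, N = n, matrix = m,
    counts = tibble::tibble(class = 0:(K - 1), tp = as.integer(tp),
                            fp = as.integer(fp), fn = as.integer(fn),
                            tn = as.integer(tn), n_true = as.integer(colSums(m)))
  )
  class(out) <- "confusion_counts"
  out
}

f1_from_counts <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  ifelse(den == 0, 0, 2 * tp / den)
}

#' Classification metrics from confusion counts
#'
#' Computes overall accuracy, pooled precision and recall, and the micro-,
#' macro- and weighted-averaged F1 scores. Micro precision/recall/F1 pool the
#' one-vs-rest counts over classes; macro averages per-class F1 with equal
#' weight; weighted averages per-class F1 by ground-truth class frequency.
#' Classes with an undefined (0/0) F1 contribute 0 and raise a warning.
#'
#' @param counts A `confusion_counts` object.
#' @return An object of class `classification_report`: list with scalar
#'   `accuracy`, `precision`, `recall`, `f1_micro`, `f1_macro`, `f1_weighted`
#'   and a tibble `per_class` (precision, recall, f1, support per class).
#' @export
classification_report <- function(counts) {
  stop_if(!inherits(counts, "confusion_counts"), "`counts` must be a confusion_counts object.")
  cc <- counts$counts
  stop_if(counts$N == 0L, "no samples.")
  tp <- cc$tp; fp <- cc$fp; fn <- cc$fn; nk <- cc$n_true
  if (any(2 * tp + fp + fn == 0)) {
    rlang::warn("class with no true or predicted samples: its F1 contributes 0.")
  }
  prec_k <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec_k <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1_k <- f1_from_counts(tp, fp, fn)
  out <- list(
    accuracy   = sum(tp) / counts$N,
    precision  = sum(tp) / sum(tp + fp),
    recall     = sum(tp) / sum(tp + fn),
    f1_micro   = 2 * sum(tp) / (2 * sum(tp) + sum(fp) + sum(fn)),
    f1_macro   = mean(f1_k),
    f1_weighted = sum(nk / counts$N * f1_k),
    per_class  = tibble::tibble(class = cc$class, precision = prec_k,
                                recall = rec_k, f1 = f1_k, support = nk)
  )
  class(out) <- "classification_report"
  out
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f\n",
              x$accuracy, x$precision, x$recall))
  cat(sprintf("F1 micro %.4f | macro %.4f | weighted %.4f\n",
              x$f1_micro, x$f1_macro, x$f1_weighted))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, precision = x$precision, recall = x$recall,
                 f1_micro = x$f1_micro, f1_macro = x$f1_macro,
                 f1_weighted = x$f1_weighted)
}

#' Dice and IoU overlap of two binary masks
#'
#' Dice = 2|P∩G| / (|P| + |G|); IoU (Jaccard) = |P∩G| / |P∪G|. When both masks
#' are empty the pair is defined as a perfect match (Dice = IoU = 1), the usual
#' convention for anatomy classes absent from a slice.
#'
#' @param pred Binary predicted mask (logical or 0/1 numeric array).
#' @param truth Binary ground-truth mask, same shape.
#' @return Named numeric vector `c(dice =, iou =)`.
#' @export
dice_iou <- function(pred, truth) {
  stop_if(!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth)),
          "`pred` and `truth` must share shape.")
  p <- as.logical(pred); g <- as.logical(truth)
  stop_if(anyNA(p) || anyNA(g), "masks must be binary with no NA.")
  inter <- sum(p & g)
  sp <- sum(p); sg <- sum(g)
  if (sp + sg == 0) return(c(dice = 1, iou = 1))
  c(dice = 2 * inter / (sp + sg), iou = inter / (sp + sg - inter))
}

#' Per-class Dice/IoU for integer-coded label maps
#'
#' One-vs-rest Dice and IoU per class plus their mean. Classes absent from both
#' prediction and ground truth score 1 and are flagged in the `absent` column.
#' The mean excludes the background class (class 0) by default, as overlap
#' tables for anatomical structures conventionally list foreground regions only.
#'
#' @param pred Integer label map.
#' @param truth Integer label map, same shape.
#' @param n_classes Number of classes `K` (labels in `[0, K)`).
#' @param include_background Include class 0 in the mean? Default `FALSE`.
#' @return List with tibble `per_class` (class, dice, iou, absent) and scalars
#'   `mean_dice`, `mean_iou`.
#' @export
multiclass_dice_iou <- function(pred, truth, n_classes, include_background = FALSE) {
  stop_if(!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth)),
          "`pred` and `truth` must share shape.")
  stop_if(!is_count(n_classes, min = 2), "`n_classes` must be >= 2.")
  per <- purrr::map(0:(n_classes - 1), function(k) {
    s <- dice_iou(pred == k, truth == k)
    tibble::tibble(class = k, dice = s[["dice"]], iou = s[["iou"]],
                   absent = sum(pred == k) + sum(truth == k) == 0)
  })
  per <- dplyr::bind_rows(per)
  keep <- if (include_background) per else per[per$class != 0L, ]
  list(per_class = per,
       mean_dice = mean(keep$dice),
       mean_iou = mean(keep$iou))
}

#' Mean and population standard deviation of a score series
#'
#' Stability of a metric across runs (e.g. across sampling strides or training
#' set sizes) is summarized by the arithmetic mean and the population standard
#' deviation (divisor n, not n-1).
#'
#' @param values Numeric vector of at least two scores.
#' @return A `stability_summary`: tibble with `n`, `mean`, `std`.
#' @export
stability <- function(values) {
  stop_if(!is.numeric(values) || length(values) < 2L,
          "`values` must be a numeric vector with >= 2 entries.")
  n <- length(values)
  m <- mean(values)
  std <- sqrt(sum((values - m)^2) / n)
  out <- tibble::tibble(n = n, mean = m, std = std)
  class(out) <- c("stability_summary", class(out))
  out
}
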