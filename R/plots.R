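# ggplot2 visual summaries for fitted objects and reports.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_text
#'   scale_fill_gradient labs theme_minimal
#' @export
ggplot2::autoplot

#' @export
autoplot.mae_checkpoint <- function(object, ...) {
  ggplot(object$loss_curve, aes(x = .data$epoch, y = .data$loss)) +
    geom_line(color = "#2c7fb8") +
    labs(x = "epoch", y = "coverage-weighted reconstruction loss",
         title = "MAE pretraining") +
    theme_minimal()
}

#' @export
autoplot.segmenter_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$training_log, -"epoch",
                            names_to = "series", values_to = "value")
  ggplot(df, aes(x = .data$epoch, y = .data$value, color = .data$series)) +
    geom_line() +
    labs(x = "epoch", y = NULL, title = "Segmenter training") +
    theme_minimal()
}

#' @export
autoplot.probe_head <- function(object, ...) {
  ggplot(object$training_log, aes(x = .data$epoch, y = .data$loss)) +
    geom_line(color = "#756bb1") +
    labs(x = "epoch", y = "cross-entropy", title = "Linear probe training") +
    theme_minimal()
}

#' Confusion-matrix heat map
#'
#' Rows are predicted labels, columns ground truth.
#'
#' @param counts A `confusion_counts` object.
#' @param class_names Optional class names.
#' @return A ggplot object.
#' @export
plot_confusion <- function(counts, class_names = NULL) {
  m <- counts$matrix
  nm <- class_names %||% rownames(m)
  df <- tidyr::expand_grid(pred = factor(nm, levels = rev(nm)),
                           truth = factor(nm, levels = nm))
  df$n <- as.vector(t(m[rev(seq_len(nrow(m))), ]))
  ggplot(df, aes(x = .data$truth, y = .data$pred, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n), size = 3) +
    scale_fill_gradient(low = "white", high = "#2c7fb8") +
    labs(x = "ground truth", y = "predicted") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
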