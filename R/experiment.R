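# Orchestration: experiment presets and configs (YAML round-trip), end-to-end
# desk-scale pipelines (phantom -> pretrain -> probe or segment -> metrics),
# and sweep drivers over stride / sample size / width / fusion strategy with
# stability summaries. Per-stage seeds derive from the master seed so stages
# are independently reproducible.

#' Experiment configuration
#'
#' @param preset `"tiny"` (desk scale, the test default: 64 px images, 4-layer
#'   width-64 encoder, 16-channel depth-3 U-Net, batch 8) or `"vitbase"`
#'   (full-scale mirror: 224 px, 12-layer width-768 encoder, 64-channel
#'   depth-4 U-Net, batch 48).
#' @param task `"classification"`, `"skull_strip"` or `"anatomy"`.
#' @param seed Master seed.
#' @param epochs Named list of per-stage epochs (pretrain, probe, segment).
#' @param lr,batch_size Optimizer defaults (AdamW; full-scale defaults are
#'   lr 1e-4 and batch 48).
#' @param strategy Fusion strategy for segmentation tasks.
#' @param stride_k,n_slices_per_sequence,n_volumes Few-shot sampling knobs.
#' @param output_dir Run directory.
#' @return An `experiment_config` list, YAML-serializable and round-trippable.
#' @export
experiment_config <- function(preset = c("tiny", "vitbase"),
                              task = c("classification", "skull_strip", "anatomy"),
                              seed = 1L,
                              epochs = list(pretrain = 12, probe = 300, segment = 24),
                              lr = NULL, batch_size = NULL,
                              strategy = "concat", stride_k = 7,
                              n_slices_per_sequence = 10, n_volumes = 2,
                              output_dir = tempfile("maefunet-run-")) {
  preset <- match.arg(preset)
  task <- match.arg(task)
  base <- if (preset == "tiny") {
    list(lr = 1e-3, batch_size = 8, base_channels = 16L, depth = 3L,
         tap_layers = c(1L, 2L, 3L, 4L), grid_size = 64L)
  } else {
    list(lr = 1e-4, batch_size = 48, base_channels = 64L, depth = 4L,
         tap_layers = c(1L, 3L, 6L, 9L, 12L), grid_size = 224L)
  }
  cfg <- list(preset = preset, task = task, seed = as.integer(seed),
              epochs = epochs, lr = lr %||% base$lr,
              batch_size = batch_size %||% base$batch_size,
              base_channels = base$base_channels, depth = base$depth,
              tap_layers = base$tap_layers, grid_size = base$grid_size,
              strategy = strategy, stride_k = as.integer(stride_k),
              n_slices_per_sequence = as.integer(n_slices_per_sequence),
              n_volumes = as.integer(n_volumes), output_dir = output_dir)
  class(cfg) <- "experiment_config"
  cfg
}

#' Write / read an experiment config as YAML
#'
#' @param config An `experiment_config`.
#' @param path YAML file path.
#' @return `read_experiment_config` returns the config; `write_experiment_config`
#'   returns `path` invisibly.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$tap_layers <- as.integer(cfg$tap_layers)
  class(cfg) <- "experiment_config"
  cfg
}

vit_config_for <- function(config) {
  vit_config(config$preset)
}

phantom_dataset_for <- function(config, n_train_volumes = 2) {
  spec <- phantom_spec(grid_size = config$grid_size,
                       seed = derive_seed(config$seed, "phantom"))
  generate_phantom(spec)
}

#' Run an end-to-end desk-scale experiment
#'
#' Stages (phantom generation, MAE pretraining, then probing or segmentation
#' and metrics) run in order with per-stage seeds derived from the master
#' seed. Each stage writes its artifacts into the run directory together with
#' the resolved config, a config hash, and a state file that marks completed
#' stages so interrupted runs can be diagnosed.
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress?
#' @return List with `run_dir`, `checkpoint`, the task `fit`, and a `metrics`
#'   list (classification report or Dice/IoU summary).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_experiment_config(config, file.path(config$output_dir, "config.yaml"))
  state_path <- file.path(config$output_dir, "state.json")
  mark <- function(stage) {
    st <- if (file.exists(state_path)) jsonlite::read_json(state_path) else list()
    st[[stage]] <- TRUE
    st$config_hash <- rlang::hash(unclass(config))
    jsonlite::write_json(st, state_path, auto_unbox = TRUE)
  }
  vcfg <- vit_config_for(config)

  # stage 1: phantom
  vols <- phantom_dataset_for(config)
  # second phantom (different anatomy seed) as a held-out source
  spec2 <- phantom_spec(grid_size = config$grid_size,
                        seed = derive_seed(config$seed, "phantom", 2))
  vols2 <- generate_phantom(spec2)
  mark("phantom")
  if (verbose) message("phantom generated")

  # stage 2: pretraining on all sequences of the first phantom
  pre_samples <- purrr::flatten(purrr::map(names(vols), function(sq) {
    remap_volume_to_slices(vols[[sq]], axes = "axial", min_foreground = 0,
                           volume_id = paste0("p1-", sq))
  }))
  pre_ds <- as_slice_dataset(pre_samples)
  ckpt <- mae_pretrain(pre_ds, vcfg, epochs = config$epochs$pretrain,
                       batch_size = config$batch_size, lr = config$lr,
                       seed = derive_seed(config$seed, "pretrain"),
                       verbose = verbose)
  save_checkpoint(ckpt, file.path(config$output_dir, "mae.rds"))
  mark("pretrain")
  if (verbose) message("pretraining done")

  fit <- NULL; metrics <- NULL
  if (config$task == "classification") {
    vbs <- purrr::imap(vols, function(v, sq) {
      out <- list(v, vols2[[sq]])
      names(out) <- paste0(sq, c("_a", "_b"))
      out
    })
    split <- build_classification_split(vbs, config$n_slices_per_sequence,
                                        seed = derive_seed(config$seed, "split"))
    tr <- split$manifest$split == "train"
    ds_tr <- as_slice_dataset(split$samples[tr])
    ds_te <- as_slice_dataset(split$samples[!tr])
    fit <- train_probe(ds_tr, ckpt, n_classes = length(vols),
                       class_names = names(vols),
                       epochs = config$epochs$probe, lr = 1e-2,
                       seed = derive_seed(config$seed, "probe"))
    pred <- predict_probe(fit, extract_cls(ckpt, ds_te$images))
    cc <- confusion_counts(ds_te$sequence_label, pred$label, length(vols))
    metrics <- list(report = classification_report(cc), confusion = cc)
  } else {
    task <- if (config$task == "skull_strip") "skull_strip" else "anatomy"
    seq1 <- names(vols)[1]
    split <- build_segmentation_split(
      list(p1 = vols[[seq1]], p2 = vols2[[seq1]]),
      task = task, stride_k = config$stride_k, n_volumes = config$n_volumes,
      seed = derive_seed(config$seed, "split"))
    n_classes <- if (task == "skull_strip") 2L else
      max(vapply(split$train, function(s) max(s$labels), numeric(1))) + 1L
    fc <- fusion_config(strategy = config$strategy, tap_layers = config$tap_layers,
                        base_channels = config$base_channels, depth = config$depth,
                        n_classes = n_classes, image_size = vcfg$image_size)
    ds_tr <- as_slice_dataset(split$train)
    ds_te <- as_slice_dataset(split$test)
    fit <- train_segmenter(ds_tr, ckpt, fc, epochs = config$epochs$segment,
                           batch_size = config$batch_size, lr = config$lr,
                           seed = derive_seed(config$seed, "segment"),
                           verbose = verbose)
    # evaluate on a capped subset of test slices to keep desk runs short
    n_eval <- min(length(ds_te$images), 24L)
    set.seed(derive_seed(config$seed, "eval"))
    eid <- sample(length(ds_te$images), n_eval)
    pred <- predict_segmenter(fit, ckpt, ds_te$images[eid])
    scores <- purrr::map(seq_len(n_eval), function(i) {
      m <- multiclass_dice_iou(pred$labels[i, , ], ds_te$labels[[eid[i]]], n_classes)
      tibble::tibble(slice = eid[i], dice = m$mean_dice, iou = m$mean_iou)
    })
    scores <- dplyr::bind_rows(scores)
    metrics <- list(scores = scores,
                    mean_dice = mean(scores$dice), mean_iou = mean(scores$iou))
  }
  mark(config$task)
  mj <- if (config$task == "classification") {
    as.list(glance(metrics$report))
  } else {
    list(mean_dice = metrics$mean_dice, mean_iou = metrics$mean_iou)
  }
  jsonlite::write_json(mj, file.path(config$output_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  list(run_dir = config$output_dir, checkpoint = ckpt, fit = fit, metrics = metrics)
}

#' Sweep one experiment axis
#'
#' Runs the pipeline once per axis value (`stride`, `n_slices`, `n_volumes`,
#' `width` or `fusion`), with per-run seeds derived from the master seed, and
#' summarizes the headline score with [stability()] (mean and population std).
#' For the `width` and `fusion` axes the trainable parameter count is included,
#' giving the ablation-table shape (score columns plus a parameter column).
#'
#' @param config Base [experiment_config()].
#' @param axis One of `"stride"`, `"n_slices"`, `"n_volumes"`, `"width"`,
#'   `"fusion"`.
#' @param values Axis values (non-empty).
#' @param run_fn Function executed per run, default [run_experiment()];
#'   injectable for dry runs.
#' @return List with tibble `table` (one row per value, plus score and
#'   parameter columns where applicable) and `stability` summary of the score.
#' @export
sweep_axis <- function(config, axis = c("stride", "n_slices", "n_volumes", "width", "fusion"),
                  values, run_fn = run_experiment) {
  axis <- match.arg(axis)
  stop_if(length(values) == 0L, "empty sweep axis.")
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    v <- values[[i]]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("sweep-", axis), i)
    cfg$output_dir <- file.path(config$output_dir, paste0(axis, "-", v))
    if (axis == "stride") cfg$stride_k <- as.integer(v)
    if (axis == "n_slices") cfg$n_slices_per_sequence <- as.integer(v)
    if (axis == "n_volumes") cfg$n_volumes <- as.integer(v)
    if (axis == "width") cfg$base_channels <- as.integer(v)
    if (axis == "fusion") cfg$strategy <- as.character(v)
    res <- run_fn(cfg)
    score <- if (!is.null(res$metrics$mean_dice)) {
      tibble::tibble(dice = res$metrics$mean_dice, iou = res$metrics$mean_iou)
    } else {
      tibble::tibble(accuracy = res$metrics$report$accuracy)
    }
    row <- dplyr::bind_cols(tibble::tibble(value = v), score)
    if (axis %in% c("width", "fusion") && !is.null(res$fit)) {
      row$n_params <- n_trainable(res$fit$model %||% res$fit)
    }
    rows[[i]] <- row
  }
  table <- dplyr::bind_rows(rows)
  score_col <- setdiff(names(table), c("value", "n_params"))[1]
  list(table = table, stability = stability(table[[score_col]]))
}
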