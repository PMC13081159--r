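# Training, evaluation, prediction, and run comparison.
#
# Training follows the protocol: RMSprop (lr 1e-4), batch size 8, a fixed
# budget of optimizer steps (default 1000), optional augmentation, and early
# stopping monitoring validation mIoU every `eval_every` steps with a
# patience counter. The best-validation parameter snapshot is retained.

#' Training configuration
#'
#' @param batch_size images per optimizer step (sampled with replacement
#'   when the training set is smaller).
#' @param total_steps total optimizer steps.
#' @param optimizer only `"rmsprop"`.
#' @param learning_rate initial learning rate.
#' @param early_stopping_patience number of consecutive non-improving
#'   validation checks tolerated before stopping (0 = stop at the first
#'   non-improving check).
#' @param eval_every steps between validation checks.
#' @param loss `"mwl"`, `"ce"`, or `"dice"`.
#' @param loss_params list of MWL parameters (`w_b`, `w_m`, `w_0`,
#'   `kernel_size`, `iterations`).
#' @param augment apply training-time augmentation?
#' @param seed global seed: model initialization, batch shuffling, and
#'   augmentation all derive from it.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 8L, total_steps = 1000L,
                         optimizer = "rmsprop", learning_rate = 1e-4,
                         early_stopping_patience = 50L, eval_every = 50L,
                         loss = c("mwl", "ce", "dice"),
                         loss_params = list(w_b = 1, w_m = 2, w_0 = 1,
                                            kernel_size = 3L,
                                            iterations = 1L),
                         augment = TRUE, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(batch_size >= 1L, total_steps >= 1L, learning_rate > 0,
            early_stopping_patience >= 0L, eval_every >= 1L,
            identical(optimizer, "rmsprop"))
  structure(list(batch_size = as.integer(batch_size),
                 total_steps = as.integer(total_steps),
                 optimizer = optimizer, learning_rate = learning_rate,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 eval_every = as.integer(eval_every), loss = loss,
                 loss_params = loss_params, augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "train_config")
}

.batch_arrays <- function(samples) {
  d <- dim(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, dim = c(d[1], d[2], 1, n))
  y <- array(0, dim = c(d[1], d[2], 1, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- samples[[i]]$image
    y[, , 1, i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

.loss_pair <- function(name, loss_params) {
  switch(name,
         mwl = list(
           value = function(p, y) mwl_loss(p, y, mwl_params = loss_params),
           grad = function(p, y) mwl_loss_grad(p, y, mwl_params = loss_params)),
         ce = list(value = ce_loss, grad = ce_loss_grad),
         dice = list(value = dice_loss, grad = dice_loss_grad),
         stop("unknown loss: ", name))
}

.snapshot_state <- function(model) {
  list(params = lapply(collect_params(model), function(p) p$value),
       bn = lapply(collect_bn_layers(model), function(l) {
         list(mean = l$running_mean, var = l$running_var)
       }))
}

.restore_state <- function(model, state) {
  params <- collect_params(model)
  for (i in seq_along(params)) params[[i]]$value <- state$params[[i]]
  bns <- collect_bn_layers(model)
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- state$bn[[i]]$mean
    bns[[i]]$running_var <- state$bn[[i]]$var
  }
  invisible(model)
}

#' Mean per-image mIoU of a model on a set of samples
#'
#' @param model an `hfsunet_model`.
#' @param samples list of samples.
#' @param threshold probability threshold for the predicted mask.
#' @return mean per-image mIoU in percent.
#' @export
validation_miou <- function(model, samples, threshold = 0.5) {
  mean(vapply(samples, function(s) {
    pm <- predict_mask(model, s$image, threshold = threshold)
    miou(confusion_counts(pm, s$mask))
  }, numeric(1)))
}

#' Train a model
#'
#' @param train_samples list of training samples (all the same size, with
#'   `H`, `W` divisible by `2^(levels-1)`).
#' @param val_samples optional validation samples for early stopping; when
#'   `NULL`, training runs for the full step budget.
#' @param config a [train_config()].
#' @param model_cfg a [model_config()].
#' @param log_csv optional path for the per-step loss / per-check metric log.
#' @param verbose print progress lines?
#' @return list of class `hfsunet_fit`: the trained `model` (best validation
#'   snapshot when validation was used), `history` data.frame (step, loss,
#'   val_miou), `best_step`, and the configs.
#' @export
train <- function(train_samples, val_samples = NULL,
                  config = train_config(), model_cfg = model_config(),
                  log_csv = NULL, verbose = FALSE) {
  if (length(train_samples) == 0) stop("empty training set")
  set.seed(config$seed)
  model <- build_model(model_cfg)
  params <- collect_params(model)
  lp <- .loss_pair(config$loss, config$loss_params)
  set.seed(config$seed + 1L)  # batching/augmentation stream

  n <- length(train_samples)
  history <- data.frame(step = integer(0), loss = numeric(0),
                        val_miou = numeric(0))
  best <- list(miou = -Inf, state = NULL, step = 0L)
  bad_checks <- 0L
  stopped <- FALSE

  for (step in seq_len(config$total_steps)) {
    idx <- sample.int(n, config$batch_size, replace = n < config$batch_size)
    batch <- train_samples[idx]
    if (config$augment) batch <- lapply(batch, augment)
    ba <- .batch_arrays(batch)
    x <- tensor(ba$x)
    pred <- model_forward(model, x, training = TRUE)
    loss_val <- lp$value(pred$value, ba$y)
    if (!is.finite(loss_val)) {
      stop("non-finite loss at step ", step,
           " (loss=", loss_val, "); check inputs and learning rate")
    }
    zero_grads(params)
    backward(pred, seed = lp$grad(pred$value, ba$y))
    rmsprop_step(params, lr = config$learning_rate)

    val_m <- NA_real_
    if (!is.null(val_samples) && length(val_samples) > 0 &&
        step %% config$eval_every == 0L) {
      val_m <- validation_miou(model, val_samples)
      if (val_m > best$miou) {
        best <- list(miou = val_m, state = .snapshot_state(model),
                     step = step)
        bad_checks <- 0L
      } else {
        bad_checks <- bad_checks + 1L
        if (bad_checks > config$early_stopping_patience) stopped <- TRUE
      }
    }
    history <- rbind(history,
                     data.frame(step = step, loss = loss_val,
                                val_miou = val_m))
    if (verbose && (step %% 25L == 0L || !is.na(val_m))) {
      message(sprintf("step %4d  loss %.5f%s", step, loss_val,
                      if (!is.na(val_m)) sprintf("  val mIoU %.3f", val_m)
                      else ""))
    }
    if (stopped) break
  }
  if (!is.null(best$state)) .restore_state(model, best$state)
  if (!is.null(log_csv)) utils::write.csv(history, log_csv, row.names = FALSE)
  structure(list(model = model, history = history,
                 best_step = if (is.null(best$state)) nrow(history)
                 else best$step,
                 early_stopped = stopped, train_config = config,
                 model_config = model_cfg),
            class = "hfsunet_fit")
}

#' Predict a binary mask for one image
#'
#' Images whose size is not divisible by `2^(levels-1)` are reflect-padded
#' (with a warning) and the prediction cropped back.
#'
#' @param model an `hfsunet_model`.
#' @param image grayscale matrix in `[0, 1]`.
#' @param threshold probability cutoff (default 0.5).
#' @param probabilities return the probability map instead of a mask?
#' @return binary matrix (or probability matrix).
#' @export
predict_mask <- function(model, image, threshold = 0.5,
                         probabilities = FALSE) {
  div <- 2L^(model$config$levels - 1L)
  d <- dim(image)
  if (any(d %% div != 0L)) {
    warning("padding ", d[1], "x", d[2], " input to a multiple of ", div)
    image <- pad_to_multiple(image, div)$image
  }
  p <- model_forward(model, image, training = FALSE)[, , 1, 1]
  p <- p[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  if (probabilities) p else (p >= threshold) + 0
}

#' Evaluate a model on a sample set
#'
#' @param model an `hfsunet_model` (or an `hfsunet_fit`).
#' @param samples list of samples.
#' @param out_csv optional path for the per-image CSV (one row per image:
#'   id, mIoU, Dice, F1, ACC, lesion counts).
#' @param threshold probability cutoff.
#' @param small_threshold small-lesion area threshold in pixels.
#' @return list with `per_image` (data.frame), `aggregates` (micro and macro
#'   mIoU/Dice/F1/ACC), and `small_lesions` (total / detected / missed gt
#'   components under the threshold).
#' @export
evaluate <- function(model, samples, out_csv = NULL, threshold = 0.5,
                     small_threshold = 100L) {
  if (inherits(model, "hfsunet_fit")) model <- model$model
  rows <- list()
  counts <- list()
  for (s in samples) {
    pm <- predict_mask(model, s$image, threshold = threshold)
    rows[[length(rows) + 1L]] <- image_metrics(pm, s$mask, id = s$id,
                                               small_threshold = small_threshold)
    counts[[length(counts) + 1L]] <- confusion_counts(pm, s$mask)
  }
  per_image <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(per_image, out_csv,
                                          row.names = FALSE)
  list(per_image = per_image,
       aggregates = aggregate_metrics(counts),
       small_lesions = list(total = sum(per_image$n_small_lesions),
                            detected = sum(per_image$n_small_detected),
                            missed = sum(per_image$n_small_lesions) -
                              sum(per_image$n_small_detected)))
}

#' Predict masks for a directory of images
#'
#' Writes one 0/255 PNG mask per input image (same stems); idempotent for a
#' fixed checkpoint.
#'
#' @param model an `hfsunet_model` or `hfsunet_fit`.
#' @param image_dir directory of grayscale PNGs.
#' @param out_dir output directory for mask PNGs.
#' @param threshold probability cutoff; values above 1 give empty masks,
#'   0 gives full masks.
#' @param write_probabilities also write `*_prob.png` probability maps?
#' @return invisibly, the vector of written mask paths.
#' @export
predict_dir <- function(model, image_dir, out_dir, threshold = 0.5,
                        write_probabilities = FALSE) {
  if (inherits(model, "hfsunet_fit")) model <- model$model
  files <- sort(list.files(image_dir, pattern = "\\.png$"))
  if (length(files) == 0) stop("no PNG images found in ", image_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (f in files) {
    img <- .read_gray_png(file.path(image_dir, f))
    prob <- predict_mask(model, img, probabilities = TRUE)
    mask <- (prob >= threshold) + 0
    out <- file.path(out_dir, f)
    png::writePNG(mask, out)
    if (write_probabilities) {
      png::writePNG(prob, file.path(out_dir, sub("\\.png$", "_prob.png", f)))
    }
    written <- c(written, out)
  }
  invisible(written)
}

# ---- checkpoints ----

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized archive holding the model
#' configuration, all parameter arrays (in deterministic collection order),
#' batch-norm running statistics, and optionally the training history.
#'
#' @param model an `hfsunet_model` or `hfsunet_fit`.
#' @param path file path (`.rds`).
#' @param history optional training history to store alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  if (inherits(model, "hfsunet_fit")) {
    if (is.null(history)) history <- model$history
    model <- model$model
  }
  saveRDS(list(config = model$config, state = .snapshot_state(model),
               history = history, package_version = "hfsunet 0.1.0"),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  .restore_state(model, ck$state)
  attr(model, "history") <- ck$history
  model
}

#' Compare two evaluation runs (per-image CSVs)
#'
#' Reads two per-image metric CSVs (as written by [evaluate()]), aligns them
#' by image id, and produces the paired comparison: summary table, one-tailed
#' paired t-test (B > A), Cohen's d, and the diagnostic plots.
#'
#' @param csv_a,csv_b per-image CSV paths (model A and model B).
#' @param metric score column to compare (default `"miou"`).
#' @param names_ab arm labels.
#' @param threshold large-difference cutoff (score units).
#' @param out_dir optional output directory for the report files.
#' @return a [comparison_report()] result plus the `paired_scores` object.
#' @export
compare_runs <- function(csv_a, csv_b, metric = "miou",
                         names_ab = c("A", "B"), threshold = 0.1,
                         out_dir = NULL) {
  a <- utils::read.csv(csv_a)
  b <- utils::read.csv(csv_b)
  if (!setequal(a$id, b$id)) stop("image id mismatch between the two runs")
  b <- b[match(a$id, b$id), ]
  if (!metric %in% names(a) || !metric %in% names(b)) {
    stop("metric column '", metric, "' not present in both CSVs")
  }
  ps <- paired_scores(a[[metric]], b[[metric]], ids = a$id)
  rep <- comparison_report(ps, names_ab = names_ab, threshold = threshold,
                           out_dir = out_dir)
  rep$scores <- ps
  rep
}
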