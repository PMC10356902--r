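# Victim training regimes and evaluation.

.bundle_arrays <- function(bundle, split) {
  if (is.null(bundle[[split]]) || !length(bundle[[split]])) {
    stop("empty split: ", split)
  }
  as_image_array(bundle[[split]])
}

#' Train a victim under the baseline regime
#'
#' Trains with SGD + momentum for each learning rate in the grid, early
#' stopping on the validation loss with a plateau learning-rate scheduler,
#' and returns the checkpoint with the lowest validation loss over the grid
#' (ties broken toward the smaller rate).
#'
#' @param model Untrained `victim_model` from [build_model()].
#' @param bundle A `dataset_bundle` (train/val splits are used).
#' @param cfg A [train_config()] with regime `"baseline"`.
#' @param verbose Print per-epoch losses.
#' @return The trained `victim_model` with `training_log` and `regime` set.
#' @export
train_baseline <- function(model, bundle, cfg = train_config("baseline"),
                           verbose = FALSE) {
  stopifnot(cfg$regime == "baseline")
  tr <- .bundle_arrays(bundle, "train"); va <- .bundle_arrays(bundle, "val")
  best <- NULL
  for (lr in sort(cfg$lr_grid, decreasing = TRUE)) {
    m <- .train_core(model, tr$x, tr$y, va$x, va$y, cfg, lr, verbose = verbose)
    # ">=" so the smaller rate (visited later) wins ties
    if (is.null(best) || best$best_val_loss >= m$best_val_loss) best <- m
  }
  best$regime <- "baseline"
  best
}

#' Train a victim under the overfitting regime
#'
#' No weighted sampling, no shuffling, no scheduler, no augmentation beyond
#' normalization, a fixed epoch budget and the last checkpoint kept
#' regardless of validation loss — a deliberately leaky training setup.
#'
#' @inheritParams train_baseline
#' @param cfg A [train_config()] with regime `"overfit"`.
#' @return The trained `victim_model`.
#' @export
train_overfit <- function(model, bundle, cfg = train_config("overfit"),
                          verbose = FALSE) {
  stopifnot(cfg$regime == "overfit")
  tr <- .bundle_arrays(bundle, "train"); va <- .bundle_arrays(bundle, "val")
  m <- .train_core(model, tr$x, tr$y, va$x, va$y,
                   cfg, cfg$lr_grid[1], verbose = verbose)
  m$regime <- "overfit"
  m
}

#' Differential-privacy configuration for DP-SGD
#'
#' @param max_grad_norm Per-sample gradient clipping bound C.
#' @param noise_multiplier Gaussian noise multiplier sigma (noise std is
#'   sigma * C on the summed clipped gradient). `NULL` auto-calibrates sigma
#'   so that the planned number of steps spends at most `target_epsilon`.
#' @param target_epsilon Privacy budget epsilon.
#' @param delta Privacy parameter delta (must be below 1 / |train set|; the
#'   default 1e-5 assumes training sets of a few thousand samples).
#' @param accountant `"rdp"` (Poisson-subsampled Renyi accountant; the exact
#'   analytic Gaussian-mechanism bound is used when the sampling rate is 1).
#' @return A `dp_config`.
#' @export
dp_config <- function(max_grad_norm = 1.0, noise_multiplier = NULL,
                      target_epsilon = 5, delta = 1e-5, accountant = "rdp") {
  if (max_grad_norm <= 0) stop("max_grad_norm must be > 0")
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  if (!is.null(noise_multiplier) && noise_multiplier < 0) {
    stop("noise_multiplier must be >= 0")
  }
  if (!is.null(noise_multiplier) && noise_multiplier == 0 &&
      is.finite(target_epsilon)) {
    stop("noise_multiplier 0 cannot meet a finite epsilon target")
  }
  structure(list(max_grad_norm = max_grad_norm,
                 noise_multiplier = noise_multiplier,
                 target_epsilon = target_epsilon, delta = delta,
                 accountant = accountant),
            class = "dp_config")
}

#' Train a victim with DP-SGD
#'
#' Every per-sample gradient is clipped to L2 norm at most C before
#' aggregation; Gaussian noise with standard deviation sigma * C is added to
#' the summed clipped gradient before the (momentum) update. Training stops
#' after the configured epochs or as soon as the accountant reports the
#' target epsilon exhausted. The spent (epsilon, delta) is recorded on the
#' model.
#'
#' @inheritParams train_baseline
#' @param cfg A [train_config()] with regime `"dp"`.
#' @param dp A [dp_config()].
#' @return The trained `victim_model` with `spent_privacy` set.
#' @export
train_dp <- function(model, bundle, cfg = train_config("dp"),
                     dp = dp_config(), verbose = FALSE) {
  stopifnot(cfg$regime == "dp")
  if (any(vapply(model$layers, function(l) identical(l$type, "batchnorm"), TRUE))) {
    stop("batch normalization is incompatible with per-sample DP gradients")
  }
  tr <- .bundle_arrays(bundle, "train"); va <- .bundle_arrays(bundle, "val")
  n <- length(tr$y)
  if (dp$delta >= 1 / n) {
    warning("delta >= 1/|train set|; the reported guarantee is vacuous")
  }
  q <- min(1, cfg$batch_size / n)
  planned_steps <- cfg$max_epochs * ceiling(n / cfg$batch_size)
  if (is.null(dp$noise_multiplier)) {
    dp$noise_multiplier <- calibrate_noise(dp$target_epsilon, dp$delta,
                                           planned_steps, q)
  }
  m <- .train_core(model, tr$x, tr$y, va$x, va$y, cfg, cfg$lr_grid[1],
                   dp = dp, verbose = verbose)
  eps <- privacy_spent(dp, m$dp_steps, q)
  m$spent_privacy <- list(epsilon = eps, delta = dp$delta,
                          noise_multiplier = dp$noise_multiplier,
                          max_grad_norm = dp$max_grad_norm,
                          steps = m$dp_steps, sampling_rate = q)
  m$regime <- "dp"
  m
}

#' Evaluate a model on a list of labeled images
#'
#' @param model A trained `victim_model`.
#' @param split List of `labeled_image` (or a `dataset_bundle` split) — must
#'   be non-empty.
#' @param batch Prediction batch size.
#' @return An `eval_report`: weighted F1 (percent), per-class precision /
#'   recall / F1, and the confusion matrix (rows = true class).
#' @export
evaluate <- function(model, split, batch = 256L) {
  if (!length(split)) stop("empty split")
  arr <- as_image_array(split)
  nc <- model$arch$num_classes
  if (any(arr$y < 0L | arr$y >= nc)) stop("label outside [0, num_classes)")
  n <- length(arr$y)
  pred <- integer(n)
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    p <- predict_proba(model, arr$x[, , , s:e, drop = FALSE])
    pred[s:e] <- max.col(p) - 1L
  }
  eval_report(arr$y, pred, nc)
}

#' Classification report from true and predicted labels
#'
#' Weighted F1 is the support-weighted mean of per-class F1 scores, reported
#' in percent.
#'
#' @param y_true,y_pred Integer labels in `0:(num_classes-1)`.
#' @param num_classes Number of classes.
#' @return An `eval_report`.
#' @export
eval_report <- function(y_true, y_pred, num_classes) {
  cm <- matrix(0L, num_classes, num_classes,
               dimnames = list(true = 0:(num_classes - 1),
                               pred = 0:(num_classes - 1)))
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wf1 <- 100 * sum(f1 * support) / sum(support)
  structure(list(weighted_f1 = wf1, precision = 100 * prec, recall = 100 * rec,
                 per_class_f1 = 100 * f1, confusion_matrix = cm,
                 accuracy = 100 * sum(tp) / sum(cm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> weighted F1 %.2f%%  accuracy %.2f%%\n",
              x$weighted_f1, x$accuracy))
  print(x$confusion_matrix)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The weights go into a portable array archive (RDS of plain numeric
#' arrays), the architecture / regime / spent privacy into a JSON sidecar,
#' and the training log into a CSV.
#'
#' @param model A `victim_model`.
#' @param path Basename without extension; writes `<path>.weights.rds`,
#'   `<path>.json` and `<path>.log.csv`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(.par_tree(model$layers), paste0(path, ".weights.rds"))
  meta <- list(arch = unclass(model$arch), regime = model$regime,
               spent_privacy = model$spent_privacy,
               init_seed = model$init_seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(model$training_log)) {
    utils::write.csv(model$training_log, paste0(path, ".log.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arch <- arch_config(meta$arch$family, meta$arch$width, meta$arch$depth,
                      meta$arch$num_classes, meta$arch$groups)
  model <- build_model(arch, seed = if (is.null(meta$init_seed)) 1L else meta$init_seed)
  tree <- readRDS(paste0(path, ".weights.rds"))
  model$layers <- .set_par_tree(model$layers, tree)
  model$regime <- meta$regime
  model$spent_privacy <- meta$spent_privacy
  lg <- paste0(path, ".log.csv")
  if (file.exists(lg)) model$training_log <- utils::read.csv(lg)
  model
}
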