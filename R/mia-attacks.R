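# Classifier-based membership inference: attack-vector assembly, SVM and
# neural-network attack models.

#' Attack-vector specification
#'
#' Which feature groups are concatenated into the attack vector, in which
#' order, and whether each group is standardized (zero mean, unit variance
#' per feature, statistics fitted on the attack training portion only).
#' Group names follow the benchmark shorthand: `TP` target prediction, `CP`
#' concept prediction, `ATT_Occ` occlusion maps, `ATT_SAL` saliency maps,
#' `gCLM` / `pCLM` concept localization map sets.
#'
#' @param groups Ordered character subset of
#'   `c("TP", "CP", "ATT_Occ", "ATT_SAL", "gCLM", "pCLM")`.
#' @param standardize Per-group logical (recycled).
#' @return An `attack_vector_spec`.
#' @export
attack_vector_spec <- function(groups, standardize = TRUE) {
  known <- c("TP", "CP", "ATT_Occ", "ATT_SAL", "gCLM", "pCLM")
  if (!length(groups)) stop("at least one feature group is required")
  if (!all(groups %in% known)) {
    stop("unknown group(s): ", paste(setdiff(groups, known), collapse = ", "))
  }
  structure(list(groups = groups,
                 standardize = rep_len(standardize, length(groups))),
            class = "attack_vector_spec")
}

#' Parse a feature-group string like "TP+CP+pCLM"
#' @param s String of group names joined by `+`.
#' @return An `attack_vector_spec` with that group order.
#' @export
parse_feature_spec <- function(s) {
  attack_vector_spec(strsplit(s, "+", fixed = TRUE)[[1]])
}

.group_matrix <- function(features, group) {
  m <- switch(group,
    TP = features$prediction, CP = features$concept,
    ATT_Occ = features$occlusion, ATT_SAL = features$saliency,
    gCLM = features$gclm, pCLM = features$pclm)
  if (is.null(m)) stop("feature group not extracted: ", group)
  m
}

#' Assemble a balanced membership dataset of attack vectors
#'
#' Flattens and concatenates the requested feature groups per sample in spec
#' order, standardizing each feature with statistics computed on the attack
#' training portion only (zero-variance features map to 0). Samples are
#' assigned to train/val/test portions stratified by membership, so every
#' portion holds exactly as many members as non-members.
#'
#' @param features A `sample_features` with `membership` set (see
#'   [bind_features()]).
#' @param spec An [attack_vector_spec()].
#' @param split Numeric portion fractions summing to 1, e.g. `c(0.67, 0.33)`
#'   for SVM attacks or `c(0.45, 0.22, 0.33)` for neural attacks.
#' @param seed Split seed.
#' @return A `membership_dataset`: `x` (N x F), `membership` (logical),
#'   `portion` (factor `train`/`val`/`test`), `spec`, `group_dims`.
#' @export
assemble_attack_vector <- function(features, spec,
                                   split = c(0.67, 0.33), seed = 0L) {
  stopifnot(inherits(spec, "attack_vector_spec"))
  membership <- features$membership
  if (is.null(membership)) stop("features carry no membership bits")
  n <- length(membership)
  if (sum(membership) != sum(!membership)) {
    stop("membership dataset must be balanced")
  }
  mats <- lapply(spec$groups, .group_matrix, features = features)
  for (g in seq_along(mats)) {
    bad <- !is.finite(mats[[g]])
    if (any(bad)) {
      stop(sprintf("non-finite feature in group %s, sample %s",
                   spec$groups[g],
                   features$ids[which(rowSums(bad) > 0)[1]]))
    }
  }

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))
  pnames <- c("train", "val", "test")[seq_along(split)]
  if (length(split) == 2L) pnames <- c("train", "test")
  portion <- character(n)
  for (side in c(TRUE, FALSE)) {
    idx <- sample(which(membership == side))
    cuts <- round(cumsum(split) / sum(split) * length(idx))
    from <- c(1L, head(cuts, -1L) + 1L)
    for (p in seq_along(split)) {
      if (from[p] <= cuts[p]) portion[idx[from[p]:cuts[p]]] <- pnames[p]
    }
  }
  portion <- factor(portion, levels = pnames)
  tr <- portion == "train"

  xs <- vector("list", length(mats))
  for (g in seq_along(mats)) {
    m <- mats[[g]]
    if (spec$standardize[g]) {
      mu <- colMeans(m[tr, , drop = FALSE])
      sd_ <- apply(m[tr, , drop = FALSE], 2, stats::sd)
      m <- sweep(m, 2, mu)
      nz <- sd_ > 1e-12
      m[, nz] <- sweep(m[, nz, drop = FALSE], 2, sd_[nz], "/")
      m[, !nz] <- 0
    }
    xs[[g]] <- m
  }
  structure(list(x = do.call(cbind, xs), membership = membership,
                 portion = portion, spec = spec,
                 group_dims = vapply(mats, ncol, integer(1)),
                 ids = features$ids),
            class = "membership_dataset")
}

#' @export
print.membership_dataset <- function(x, ...) {
  cat("<membership_dataset>", nrow(x$x), "samples x", ncol(x$x), "features;",
      "groups", paste(x$spec$groups, collapse = "+"), "\n")
  print(table(x$portion, x$membership))
  invisible(x)
}

#' SVM membership attack
#'
#' Radial-basis SVM trained on the training portion, accuracy reported on
#' the held-out portion. Attack vectors with more than `reduce_above`
#' features are first reduced by a seeded Gaussian random projection to
#' `reduce_to` dimensions (fitted independently of the data).
#'
#' @param dataset A `membership_dataset` with a train/test split (2 parts).
#' @param seed Seed for the projection.
#' @param reduce_above,reduce_to Random-projection thresholds.
#' @return An `attack_result` with `metric = "accuracy"` in percent.
#' @export
svm_attack <- function(dataset, seed = 0L, reduce_above = 4096L,
                       reduce_to = 1024L) {
  x <- dataset$x
  if (ncol(x) > reduce_above) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(.fan_seed(seed, 7L)))
    proj <- matrix(stats::rnorm(ncol(x) * reduce_to), ncol(x), reduce_to) /
      sqrt(reduce_to)
    x <- x %*% proj
  }
  tr <- dataset$portion == "train"
  te <- dataset$portion %in% c("test")
  if (sum(tr) < 4L || sum(te) < 2L) stop("too few samples for the 67/33 split")
  fit <- e1071::svm(x[tr, , drop = FALSE],
                    factor(dataset$membership[tr], levels = c(FALSE, TRUE)),
                    kernel = "radial")
  pred <- stats::predict(fit, x[te, , drop = FALSE])
  acc <- 100 * mean(pred == factor(dataset$membership[te],
                                   levels = c(FALSE, TRUE)))
  attack_result("svm", paste(dataset$spec$groups, collapse = "+"),
                "accuracy", acc, sum(te))
}

.fit_attack_net <- function(layers, xtr, ytr, xva, yva, lr = 0.01,
                            momentum = 0.9, batch = 64L, max_epochs = 100L,
                            patience = 10L, seed = 0L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(.fan_seed(seed, 11L)))
  model <- list(layers = layers)
  params <- .par_tree(layers)
  vel <- .tree_zero_like(params)
  nd <- length(dim(xtr))
  n <- if (nd == 0L) ncol(xtr) else dim(xtr)[nd]
  take <- function(x, idx) {
    if (is.matrix(x)) x[, idx, drop = FALSE] else x[, , , idx, drop = FALSE]
  }
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    ep <- 0
    for (s in seq(1, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1L, n)]
      r <- .net_forward(model, take(xtr, idx), keep = TRUE)
      ce <- .softmax_ce(r$logits, ytr[idx])
      b <- .net_backward(model, r$caches, ce$dlogits, need_dx = FALSE)
      g <- .grads_as_tree(model$layers, b$grads)
      vel <- .tree_map2(vel, g, function(v, gr) momentum * v - lr * gr)
      params <- .tree_map2(params, vel, function(p, v) p + v)
      model$layers <- .set_par_tree(model$layers, params)
      ep <- ep + ce$loss * length(idx)
    }
    vl <- .softmax_ce(.net_forward(model, xva)$logits, yva)$loss
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep / n,
                                 val_loss = vl))
    if (vl < best_val - 1e-8) {
      best_val <- vl; best_params <- params; best_epoch <- epoch
    } else if (epoch - best_epoch >= patience) break
  }
  model$layers <- .set_par_tree(model$layers, best_params)
  model$log <- log
  model$best_epoch <- best_epoch
  model
}

#' Fully connected membership attack
#'
#' Six linear layers (input -> 512 -> 256 -> 128 -> 64 -> 32 -> 2) with ReLU
#' in between, trained with SGD for at most 100 epochs with early stopping
#' (patience 10) on the validation loss; accuracy is reported on the test
#' portion at the best-validation checkpoint.
#'
#' @param dataset A `membership_dataset` with a 45/22/33 train/val/test
#'   split.
#' @param seed Training seed.
#' @param lr Learning rate.
#' @return An `attack_result` (accuracy percent), with the training log in
#'   `$log`.
#' @export
nn_attack_fc <- function(dataset, seed = 0L, lr = 0.01) {
  parts <- split(seq_along(dataset$portion), dataset$portion)
  if (!all(c("train", "val", "test") %in% names(parts))) {
    stop("fc attack needs a train/val/test split")
  }
  fin <- ncol(dataset$x)
  widths <- c(512L, 256L, 128L, 64L, 32L)
  layers <- list()
  prev <- fin
  for (i in seq_along(widths)) {
    layers[[length(layers) + 1L]] <- nn_linear(prev, widths[i],
                                               paste0("fc", i), seed + i)
    layers[[length(layers) + 1L]] <- nn_relu(paste0("relu", i))
    prev <- widths[i]
  }
  layers[[length(layers) + 1L]] <- nn_linear(prev, 2L, "fc6", seed + 99L)
  names(layers) <- vapply(layers, function(l) l$name, "")
  xt <- t(dataset$x)   # internal layout: features x samples
  y <- as.integer(dataset$membership)
  fitted <- .fit_attack_net(layers, xt[, parts$train, drop = FALSE],
                            y[parts$train], xt[, parts$val, drop = FALSE],
                            y[parts$val], lr = lr, seed = seed)
  pred <- max.col(t(.net_forward(fitted, xt[, parts$test, drop = FALSE])$logits)) - 1L
  acc <- 100 * mean(pred == y[parts$test])
  res <- attack_result("fc", paste(dataset$spec$groups, collapse = "+"),
                       "accuracy", acc, length(parts$test))
  res$log <- fitted$log
  res$best_epoch <- fitted$best_epoch
  res
}

#' Pad and reshape an attack vector for a convolutional attack
#'
#' Zero-pads a length-F vector to the smallest `channels x s x s` volume and
#' reshapes it row-wise per channel.
#'
#' @param v Numeric vector.
#' @param channels Channel count of the target volume.
#' @return (s, s, channels) array with the trailing cells zero.
#' @export
pad_to_grid <- function(v, channels = 1L) {
  s <- ceiling(sqrt(length(v) / channels))
  out <- numeric(channels * s * s)
  out[seq_along(v)] <- v
  # fill row-major within each channel plane
  arr <- array(0, c(s, s, channels))
  for (ch in seq_len(channels)) {
    plane <- out[((ch - 1) * s * s + 1):(ch * s * s)]
    arr[, , ch] <- matrix(plane, s, s, byrow = TRUE)
  }
  arr
}

#' Convolutional membership attack
#'
#' The attack vector is zero-padded and reshaped to `channels x s x s`
#' (see [pad_to_grid()]) and fed to a small strided conv net (two
#' conv/group-norm/ReLU blocks, GAP, linear head) under the same 45/22/33
#' protocol as the fully connected attack.
#'
#' @inheritParams nn_attack_fc
#' @param channels Channels of the reshaped input.
#' @return An `attack_result` (accuracy percent).
#' @export
nn_attack_cnn <- function(dataset, seed = 0L, channels = 1L, lr = 0.01) {
  parts <- split(seq_along(dataset$portion), dataset$portion)
  if (!all(c("train", "val", "test") %in% names(parts))) {
    stop("cnn attack needs a train/val/test split")
  }
  n <- nrow(dataset$x)
  g0 <- pad_to_grid(dataset$x[1, ], channels)
  s <- dim(g0)[1]
  # internal layout (C, H, W, N)
  xall <- array(0, c(channels, s, s, n))
  for (i in seq_len(n)) {
    xall[, , , i] <- aperm(pad_to_grid(dataset$x[i, ], channels), c(3, 1, 2))
  }
  layers <- list(
    nn_conv(channels, 8L, 3L, 2L, 1L, "conv1", seed),
    nn_groupnorm(8L, 4L, "gn1"),
    nn_relu("relu1"),
    nn_conv(8L, 16L, 3L, 2L, 1L, "conv2", seed + 1L),
    nn_groupnorm(16L, 4L, "gn2"),
    nn_relu("relu2"),
    nn_gap("gap"),
    nn_linear(16L, 2L, "fc", seed + 2L))
  names(layers) <- vapply(layers, function(l) l$name, "")
  y <- as.integer(dataset$membership)
  fitted <- .fit_attack_net(layers, xall[, , , parts$train, drop = FALSE],
                            y[parts$train],
                            xall[, , , parts$val, drop = FALSE],
                            y[parts$val], lr = lr, seed = seed)
  pred <- max.col(t(.net_forward(fitted,
                                 xall[, , , parts$test, drop = FALSE])$logits)) - 1L
  acc <- 100 * mean(pred == y[parts$test])
  res <- attack_result("cnn", paste(dataset$spec$groups, collapse = "+"),
                       "accuracy", acc, length(parts$test))
  res$log <- fitted$log
  res
}

#' Attack result record
#'
#' @param attack Attack kind (`metric`, `svm`, `fc`, `cnn`).
#' @param features Feature description string.
#' @param metric `"auc"` or `"accuracy"`.
#' @param value Value in percent.
#' @param n Number of evaluated samples.
#' @return An `attack_result`.
#' @export
attack_result <- function(attack, features, metric, value, n) {
  if (!is.na(value) && (value < 0 || value > 100)) {
    stop("attack value must lie in [0, 100]")
  }
  structure(list(attack = attack, features = features, metric = metric,
                 value = value, n = n),
            class = "attack_result")
}

#' @export
print.attack_result <- function(x, ...) {
  cat(sprintf("<attack_result> %s [%s]: %s %.1f%% (n=%d)\n", x$attack,
              x$features, x$metric, x$value, x$n))
  invisible(x)
}
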