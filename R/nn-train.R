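# SGD training loop shared by the three victim regimes.

#' Training configuration
#'
#' Regime defaults: the baseline regime searches the learning-rate grid
#' {0.1, 0.01, 0.001} with batch 128, momentum 0.9, up to 200 epochs,
#' early stopping with patience 30 on the validation loss, a plateau
#' scheduler with patience 10, light augmentation and weighted sampling, and
#' keeps the checkpoint with the lowest validation loss. The overfit regime
#' trains 50 epochs with no early stopping, no scheduler, no shuffling, no
#' weighted sampling and no augmentation beyond normalization, and keeps the
#' last checkpoint. The dp regime mirrors the baseline data handling but is
#' optimized with DP-SGD (see [train_dp()]).
#'
#' @param regime `"baseline"`, `"overfit"` or `"dp"`.
#' @param lr_grid Learning rates to search (each fully trained; lowest best
#'   validation loss wins, ties toward the smaller rate).
#' @param batch_size,momentum,max_epochs Optimizer settings.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (`Inf` disables).
#' @param plateau_patience Epochs without improvement before the learning
#'   rate is divided by 10 (`Inf` disables).
#' @param augmentation_level `"none"`, `"light"` (flips), `"medium"` (flips +
#'   color jitter) or `"heavy"` (flips + jitter + small translations).
#' @param imbalance_mode `"weighted_sampling"`, `"weighted_loss"`,
#'   `"undersampling"` or `"none"`.
#' @param shuffle Reshuffle sample order each epoch.
#' @param keep `"best"` (lowest validation loss) or `"last"` checkpoint.
#' @param seed Seed controlling sampling, augmentation and batch order.
#' @return A `train_config`.
#' @export
train_config <- function(regime = c("baseline", "overfit", "dp"),
                         lr_grid = NULL, batch_size = 128L, momentum = 0.9,
                         max_epochs = NULL, early_stop_patience = NULL,
                         plateau_patience = NULL, augmentation_level = NULL,
                         imbalance_mode = NULL, shuffle = NULL, keep = NULL,
                         seed = 0L) {
  regime <- match.arg(regime)
  def <- switch(regime,
    baseline = list(lr_grid = c(0.1, 0.01, 0.001), max_epochs = 200L,
                    early_stop_patience = 30, plateau_patience = 10,
                    augmentation_level = "light",
                    imbalance_mode = "weighted_sampling",
                    shuffle = TRUE, keep = "best"),
    overfit = list(lr_grid = 0.01, max_epochs = 50L,
                   early_stop_patience = Inf, plateau_patience = Inf,
                   augmentation_level = "none", imbalance_mode = "none",
                   shuffle = FALSE, keep = "last"),
    dp = list(lr_grid = 0.05, max_epochs = 20L,
              early_stop_patience = Inf, plateau_patience = Inf,
              augmentation_level = "light",
              imbalance_mode = "weighted_sampling",
              shuffle = TRUE, keep = "last"))
  pick <- function(x, d) if (is.null(x)) d else x
  structure(list(regime = regime,
                 lr_grid = pick(lr_grid, def$lr_grid),
                 batch_size = as.integer(batch_size),
                 momentum = momentum,
                 max_epochs = as.integer(pick(max_epochs, def$max_epochs)),
                 early_stop_patience = pick(early_stop_patience, def$early_stop_patience),
                 plateau_patience = pick(plateau_patience, def$plateau_patience),
                 augmentation_level = match.arg(pick(augmentation_level, def$augmentation_level),
                                                c("none", "light", "medium", "heavy")),
                 imbalance_mode = match.arg(pick(imbalance_mode, def$imbalance_mode),
                                            c("weighted_sampling", "weighted_loss",
                                              "undersampling", "none")),
                 shuffle = pick(shuffle, def$shuffle),
                 keep = pick(keep, def$keep),
                 seed = as.integer(seed)),
            class = "train_config")
}

.augment_batch <- function(x, level) {
  if (level == "none") return(x)
  d <- dim(x); n <- d[4]
  for (i in seq_len(n)) {
    if (stats::runif(1) < 0.5) x[, , , i] <- x[d[1]:1, , , i]
    if (stats::runif(1) < 0.5) x[, , , i] <- x[, d[2]:1, , i]
    if (level %in% c("medium", "heavy")) {
      sc <- stats::runif(3, 0.92, 1.08)
      for (ch in 1:3) x[, , ch, i] <- pmin(pmax(x[, , ch, i] * sc[ch], 0), 1)
    }
    if (level == "heavy") {
      sh <- sample(-3:3, 2, replace = TRUE)
      xi <- x[, , , i]
      out <- array(0.5, d[1:3])
      rs <- max(1, 1 + sh[1]):min(d[1], d[1] + sh[1])
      cs <- max(1, 1 + sh[2]):min(d[2], d[2] + sh[2])
      out[rs, cs, ] <- xi[rs - sh[1], cs - sh[2], ]
      x[, , , i] <- out
    }
  }
  x
}

.eval_loss <- function(model, x, y, class_weights = NULL, batch = 256L) {
  n <- length(y)
  tot <- 0; wtot <- 0; correct <- 0
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    xb <- .to_internal(x[, , , s:e, drop = FALSE])
    r <- .net_forward(model, xb)
    ce <- .softmax_ce(r$logits, y[s:e], class_weights)
    w <- if (is.null(class_weights)) e - s + 1 else sum(class_weights[y[s:e] + 1L])
    tot <- tot + ce$loss * w; wtot <- wtot + w
    correct <- correct + sum(max.col(t(r$logits)) - 1L == y[s:e])
  }
  list(loss = tot / wtot, acc = correct / n)
}

# one full SGD (or DP-SGD) training run at a fixed initial learning rate
.train_core <- function(model, train_x, train_y, val_x, val_y, cfg, lr,
                        dp = NULL, verbose = FALSE) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(.fan_seed(cfg$seed, 2L)))

  n <- length(train_y)
  if (n == 0L || length(val_y) == 0L) stop("empty training or validation split")
  nc <- model$arch$num_classes
  cw <- NULL
  freq <- tabulate(train_y + 1L, nbins = nc)
  if (cfg$imbalance_mode == "weighted_loss") cw <- sum(freq) / (nc * pmax(freq, 1))
  if (cfg$imbalance_mode == "undersampling") {
    m <- min(freq[freq > 0])
    keep_idx <- unlist(lapply(which(freq > 0) - 1L, function(cl) {
      idx <- which(train_y == cl)
      if (length(idx) > m) sample(idx, m) else idx
    }))
    train_x <- train_x[, , , keep_idx, drop = FALSE]
    train_y <- train_y[keep_idx]
    n <- length(train_y)
    freq <- tabulate(train_y + 1L, nbins = nc)
  }
  samp_prob <- NULL
  if (cfg$imbalance_mode == "weighted_sampling") {
    samp_prob <- (1 / pmax(freq, 1))[train_y + 1L]
    samp_prob <- samp_prob / sum(samp_prob)
  }

  params <- .par_tree(model$layers)
  vel <- .tree_zero_like(params)
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  cur_lr <- lr
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), lr = numeric(),
                    batch_hash = numeric())
  since_improve <- 0L; since_plateau <- 0L
  steps <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- if (!is.null(samp_prob)) {
      sample.int(n, n, replace = TRUE, prob = samp_prob)
    } else if (cfg$shuffle) sample.int(n) else seq_len(n)
    ep_loss <- 0; ep_n <- 0
    for (s in seq(1, n, by = cfg$batch_size)) {
      e <- min(s + cfg$batch_size - 1L, n)
      idx <- ord[s:e]
      xb <- train_x[, , , idx, drop = FALSE]
      if (cfg$augmentation_level != "none") {
        xb <- .augment_batch(xb, cfg$augmentation_level)
      }
      xb <- .to_internal(xb)
      yb <- train_y[idx]
      if (is.null(dp)) {
        r <- .net_forward(model, xb, keep = TRUE)
        ce <- .softmax_ce(r$logits, yb, cw)
        b <- .net_backward(model, r$caches, ce$dlogits, need_dx = FALSE)
        g <- .grads_as_tree(model$layers, b$grads)
      } else {
        acc <- .tree_zero_like(params)
        bl <- 0
        for (j in seq_along(idx)) {
          xs <- xb[, , , j, drop = FALSE]
          r <- .net_forward(model, xs, keep = TRUE)
          ce <- .softmax_ce(r$logits, yb[j], cw)
          b <- .net_backward(model, r$caches, ce$dlogits, need_dx = FALSE)
          gj <- .grads_as_tree(model$layers, b$grads)
          gn <- sqrt(.tree_sumsq(gj))
          cl <- min(1, dp$max_grad_norm / max(gn, 1e-12))
          acc <- .tree_map2(acc, gj, function(a, v) a + cl * v)
          bl <- bl + ce$loss
        }
        sdn <- if (dp$noise_multiplier == 0) 0 else
          dp$noise_multiplier * dp$max_grad_norm
        g <- .tree_map(acc, function(a)
          (a + stats::rnorm(length(a)) * sdn) / length(idx))
        ce <- list(loss = bl / length(idx))
        steps <- steps + 1L
      }
      vel <- .tree_map2(vel, g, function(v, gr) cfg$momentum * v - cur_lr * gr)
      params <- .tree_map2(params, vel, function(p, v) p + v)
      model$layers <- .set_par_tree(model$layers, params)
      ep_loss <- ep_loss + ce$loss * length(idx); ep_n <- ep_n + length(idx)
    }
    vl <- .eval_loss(model, val_x, val_y, cw)
    bh <- sum(as.double(ord) * seq_along(ord)) %% 2147483647
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                                 val_loss = vl$loss, lr = cur_lr,
                                 batch_hash = bh))
    if (verbose) {
      cat(sprintf("epoch %3d  train %.4f  val %.4f  lr %.4g\n",
                  epoch, ep_loss / ep_n, vl$loss, cur_lr))
    }
    if (vl$loss < best_val - 1e-8) {
      best_val <- vl$loss; best_params <- params; best_epoch <- epoch
      since_improve <- 0L; since_plateau <- 0L
    } else {
      since_improve <- since_improve + 1L
      since_plateau <- since_plateau + 1L
    }
    if (is.finite(cfg$plateau_patience) && since_plateau >= cfg$plateau_patience) {
      cur_lr <- cur_lr / 10; since_plateau <- 0L
    }
    if (is.finite(cfg$early_stop_patience) &&
        since_improve >= cfg$early_stop_patience) break
    if (!is.null(dp) && is.finite(dp$target_epsilon)) {
      eps_now <- privacy_spent(dp, steps, min(1, cfg$batch_size / n))
      if (eps_now >= dp$target_epsilon) break
    }
  }

  if (cfg$keep == "best") model$layers <- .set_par_tree(model$layers, best_params)
  model$training_log <- log
  model$best_epoch <- if (cfg$keep == "best") best_epoch else nrow(log)
  model$best_val_loss <- best_val
  model$dp_steps <- steps
  model
}
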