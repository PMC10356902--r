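# Batched attribution/CLM computation for attack-feature extraction.
# One forward pass per window position per sample chunk serves all samples
# (occlusion) and, for p-CLMs, all concepts at once; per-image single-map
# APIs (occlusion(), p_clm()) remain the reference implementations.

.occlusion_batch <- function(model, x, targets, window, stride,
                             chunk = 200L) {
  d <- dim(x)
  S <- d[1]; n <- d[4]
  rs <- .window_starts(S, window, stride)
  cs <- .window_starts(d[2], window, stride)
  pos <- expand.grid(r = rs, c = cs)
  out <- matrix(0, n, S * d[2])
  cover <- matrix(0, S, d[2])
  for (j in seq_len(nrow(pos))) {
    ri <- pos$r[j]:(pos$r[j] + window - 1L)
    ci <- pos$c[j]:(pos$c[j] + window - 1L)
    cover[ri, ci] <- cover[ri, ci] + 1
  }
  for (s0 in seq(1, n, by = chunk)) {
    e0 <- min(s0 + chunk - 1L, n)
    idx <- s0:e0
    xb <- x[, , , idx, drop = FALSE]
    fills <- apply(xb, 4, mean)
    pr <- predict_proba(model, xb)
    clean <- pr[cbind(seq_along(idx), targets[idx])]
    acc <- matrix(0, length(idx), S * d[2])
    for (j in seq_len(nrow(pos))) {
      ri <- pos$r[j]:(pos$r[j] + window - 1L)
      ci <- pos$c[j]:(pos$c[j] + window - 1L)
      xp <- xb
      for (i in seq_along(idx)) xp[ri, ci, , i] <- fills[i]
      sc <- predict_proba(model, xp)[cbind(seq_along(idx), targets[idx])]
      cells <- as.vector(outer(ri, (ci - 1L) * S, "+"))
      acc[, cells] <- acc[, cells] + (clean - sc)
    }
    out[idx, ] <- acc / rep(as.vector(cover), each = length(idx))
  }
  out
}

.pclm_batch <- function(model, x, ensembles, window, stride,
                        blur_sigma = NULL, chunk = 200L) {
  d <- dim(x)
  S <- d[1]; n <- d[4]; K <- length(ensembles)
  if (is.null(blur_sigma)) blur_sigma <- window / 4
  rs <- .window_starts(S, window, stride)
  cs <- .window_starts(d[2], window, stride)
  pos <- expand.grid(r = rs, c = cs)
  ctr <- (window + 1) / 2
  dmat <- sqrt(outer((seq_len(window) - ctr)^2, (seq_len(window) - ctr)^2, "+"))
  wgt <- exp(-dmat^2 / (2 * (window / 4)^2))
  cover <- matrix(0, S, d[2])
  for (j in seq_len(nrow(pos))) {
    ri <- pos$r[j]:(pos$r[j] + window - 1L)
    ci <- pos$c[j]:(pos$c[j] + window - 1L)
    cover[ri, ci] <- cover[ri, ci] + 1
  }
  out <- matrix(0, n, K * S * d[2])
  for (s0 in seq(1, n, by = chunk)) {
    e0 <- min(s0 + chunk - 1L, n)
    idx <- s0:e0
    xb <- x[, , , idx, drop = FALSE]
    xblur <- xb
    for (i in seq_along(idx)) {
      xblur[, , , i] <- .gaussian_blur(xb[, , , i], blur_sigma)
    }
    clean <- concept_predictions(model, xb, ensembles)     # n x K
    acc <- array(0, c(length(idx), S * d[2], K))
    for (j in seq_len(nrow(pos))) {
      ri <- pos$r[j]:(pos$r[j] + window - 1L)
      ci <- pos$c[j]:(pos$c[j] + window - 1L)
      xp <- xb
      for (i in seq_along(idx)) {
        for (ch in 1:3) {
          xp[ri, ci, ch, i] <- wgt * xblur[ri, ci, ch, i] +
            (1 - wgt) * xb[ri, ci, ch, i]
        }
      }
      sc <- concept_predictions(model, xp, ensembles)
      cells <- as.vector(outer(ri, (ci - 1L) * S, "+"))
      for (k in seq_len(K)) {
        acc[, cells, k] <- acc[, cells, k] + (clean[, k] - sc[, k])
      }
    }
    cv <- rep(as.vector(cover), each = length(idx))
    for (k in seq_len(K)) {
      out[idx, ((k - 1) * S * d[2] + 1):(k * S * d[2])] <- acc[, , k] / cv
    }
  }
  out
}

.gclm_batch <- function(model, x, ensembles, chunk = 200L) {
  d <- dim(x)
  S <- d[1]; n <- d[4]; K <- length(ensembles)
  out <- matrix(0, n, K * S * d[2])
  for (s0 in seq(1, n, by = chunk)) {
    e0 <- min(s0 + chunk - 1L, n)
    idx <- s0:e0
    xb <- x[, , , idx, drop = FALSE]
    for (k in seq_len(K)) {
      ek <- ensembles[[k]]
      a <- activations_at(model, xb, ek$layer)
      dact <- matrix(ek$mean_direction, ncol(a), nrow(a))
      g <- .input_gradient_from_layer(model, xb, ek$layer, dact)
      for (i in seq_along(idx)) {
        v <- apply(abs(g[, , , i, drop = FALSE]), c(1, 2), max)
        out[idx[i], ((k - 1) * S * d[2] + 1):(k * S * d[2])] <- as.numeric(v)
      }
    }
  }
  out
}

.saliency_batch <- function(model, x, targets, chunk = 200L) {
  d <- dim(x)
  n <- d[4]
  out <- matrix(0, n, d[1] * d[2])
  for (s0 in seq(1, n, by = chunk)) {
    e0 <- min(s0 + chunk - 1L, n)
    idx <- s0:e0
    xb <- x[, , , idx, drop = FALSE]
    for (tg in unique(targets[idx])) {
      sel <- which(targets[idx] == tg)
      g <- input_gradient(model, xb[, , , sel, drop = FALSE], tg)
      for (j in seq_along(sel)) {
        out[idx[sel[j]], ] <- as.numeric(
          apply(abs(g[, , , j, drop = FALSE]), c(1, 2), max))
      }
    }
  }
  out
}
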