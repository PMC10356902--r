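# Concept activation vectors, concept predictions and TCAV scores.
#
# A CAV is the unit normal of a linear classifier separating the layer
# activations of concept examples from non-concept examples, oriented toward
# the concept-present side. Ensembles of CAVs are trained with different
# seeds for the balancing undersampling; the final concept direction is the
# renormalized mean of the member directions.

#' Train one concept activation vector
#'
#' Balances the two activation sets by random undersampling to the minority
#' size (seeded), splits 80/20 into train/test, fits an L2-penalized
#' logistic-loss linear classifier and returns its unit normal oriented
#' toward the positive (concept) class, together with the held-out accuracy.
#'
#' @param pos_activations,neg_activations Matrices (examples x features) of
#'   layer activations for concept and non-concept examples.
#' @param seed Seed for the undersampling and split.
#' @param lambda Ridge penalty of the logistic fit.
#' @return A `cav`: list with `direction` (unit vector), `test_accuracy`
#'   (percent), `bias`, `scale` (calibration of the signed distance),
#'   `train_seed`.
#' @export
train_cav <- function(pos_activations, neg_activations, seed = 0L,
                      lambda = 1e-3) {
  pos_activations <- as.matrix(pos_activations)
  neg_activations <- as.matrix(neg_activations)
  if (!nrow(pos_activations) || !nrow(neg_activations)) {
    stop("both concept and non-concept activations are required")
  }
  if (ncol(pos_activations) != ncol(neg_activations)) {
    stop("feature dimensions differ")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))
  m <- min(nrow(pos_activations), nrow(neg_activations))
  if (m < 5L) stop("too few examples per class (need >= 5)")
  pi_ <- sample(nrow(pos_activations), m)
  ni <- sample(nrow(neg_activations), m)
  ntr <- max(2L, floor(0.8 * m))
  xtr <- rbind(pos_activations[pi_[1:ntr], , drop = FALSE],
               neg_activations[ni[1:ntr], , drop = FALSE])
  ytr <- rep(c(1, 0), each = ntr)
  if (ntr < m) {
    xte <- rbind(pos_activations[pi_[(ntr + 1):m], , drop = FALSE],
                 neg_activations[ni[(ntr + 1):m], , drop = FALSE])
    yte <- rep(c(1, 0), each = m - ntr)
  } else {
    xte <- xtr; yte <- ytr
  }
  # constant features carry no signal; glmnet drops them from the fit
  fit <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  w <- as.numeric(fit$beta)
  b0 <- as.numeric(fit$a0)
  nw <- sqrt(sum(w * w))
  if (nw < 1e-12) stop("degenerate concept classifier (zero normal)")
  pred <- as.integer(cbind(1, xte) %*% c(b0, w) > 0)
  acc <- 100 * mean(pred == yte)
  structure(list(direction = w / nw, test_accuracy = acc,
                 bias = b0 / nw, scale = nw, train_seed = as.integer(seed)),
            class = "cav")
}

#' @export
print.cav <- function(x, ...) {
  cat(sprintf("<cav> dim %d  held-out accuracy %.1f%%  seed %d\n",
              length(x$direction), x$test_accuracy, x$train_seed))
  invisible(x)
}

#' Train an ensemble of CAVs for one concept
#'
#' Computes `n` CAVs with distinct undersampling seeds on the activations of
#' the concept-learning portion at a named layer, the renormalized mean
#' direction, the accuracy mean/std and the pairwise cosine matrix of the
#' member directions. A fresh 1-d logistic calibration of the projection on
#' the mean direction supplies [0,1] concept scores.
#'
#' @param model A `victim_model`.
#' @param layer Layer name at which activations are taken (default `"gap"`).
#' @param concept_portion List of `labeled_image` with presence labels.
#' @param concept_id Concept index (1-based) into the presence vector.
#' @param n Ensemble size (the benchmark default is 100).
#' @param min_examples Minimum positives and negatives required.
#' @param activations Optional precomputed activation matrix (examples x
#'   features) aligned with `concept_portion`, to amortize forward passes
#'   across concepts.
#' @return A `cav_ensemble`.
#' @export
cav_ensemble <- function(model, layer = "gap", concept_portion, concept_id,
                         n = 100L, min_examples = 10L, activations = NULL) {
  presence <- vapply(concept_portion,
                     function(im) im$concept_presence[[concept_id]], integer(1))
  npos <- sum(presence == 1L); nneg <- sum(presence == 0L)
  if (npos < min_examples || nneg < min_examples) {
    stop(sprintf("concept %d has too few examples (%d pos / %d neg)",
                 concept_id, npos, nneg))
  }
  if (is.null(activations)) {
    arr <- as_image_array(concept_portion)
    activations <- .batched_activations(model, arr$x, layer)
  }
  pos <- activations[presence == 1L, , drop = FALSE]
  neg <- activations[presence == 0L, , drop = FALSE]
  cavs <- lapply(seq_len(n), function(i) {
    train_cav(pos, neg, seed = .fan_seed(1000L + concept_id, 3L, i))
  })
  dirs <- do.call(rbind, lapply(cavs, function(cv) cv$direction))
  md <- colMeans(dirs)
  nmd <- sqrt(sum(md * md))
  if (nmd < 1e-12) stop("mean CAV direction vanished")
  md <- md / nmd
  accs <- vapply(cavs, function(cv) cv$test_accuracy, numeric(1))
  cosmat <- tcrossprod(dirs)   # unit rows -> cosine similarities
  # calibrate projection on the mean direction to a [0,1] concept score
  proj <- as.numeric(activations %*% md)
  cal <- unname(stats::glm.fit(cbind(1, proj), presence,
                               family = stats::binomial())$coefficients)
  structure(list(cavs = cavs, mean_direction = md,
                 accuracy_mean = mean(accs), accuracy_std = stats::sd(accs),
                 cosine_matrix = cosmat,
                 calibration = c(intercept = cal[1], slope = cal[2]),
                 concept_id = as.integer(concept_id), layer = layer, n = n),
            class = "cav_ensemble")
}

#' @export
print.cav_ensemble <- function(x, ...) {
  off <- x$cosine_matrix[upper.tri(x$cosine_matrix)]
  cat(sprintf("<cav_ensemble> concept %d @ %s: %d members, acc %.1f +/- %.1f%%, mean cos %.3f\n",
              x$concept_id, x$layer, x$n, x$accuracy_mean, x$accuracy_std,
              if (length(off)) mean(off) else 1))
  invisible(x)
}

.batched_activations <- function(model, x, layer, batch = 256L) {
  n <- dim(x)[4]
  out <- NULL
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    a <- activations_at(model, x[, , , s:e, drop = FALSE], layer)
    if (!is.matrix(a)) a <- matrix(a, ncol = e - s + 1L) # flatten spatial
    if (nrow(a) != e - s + 1L) a <- t(a)
    out <- rbind(out, a)
  }
  out
}

#' Concept prediction vector for images
#'
#' Applies each concept's calibrated mean-direction classifier to the layer
#' activation of the image(s): score_k = sigmoid(intercept_k + slope_k *
#' (activation . mean_direction_k)). A score of 0.5 marks the decision
#' boundary of the concept classifier.
#'
#' @param model A `victim_model`.
#' @param x One image (H x W x 3) or a batch (H x W x 3 x N).
#' @param ensembles List of `cav_ensemble`, one per concept, all at the same
#'   layer.
#' @return N x K matrix of concept scores in [0, 1].
#' @export
concept_predictions <- function(model, x, ensembles) {
  layers <- unique(vapply(ensembles, function(e) e$layer, ""))
  if (length(layers) != 1L) stop("ensembles disagree on the activation layer")
  a <- activations_at(model, .as_batch(x), layers)
  if (!is.matrix(a)) stop("concept layer must yield feature vectors")
  scores <- vapply(ensembles, function(e) {
    z <- e$calibration[["intercept"]] +
      e$calibration[["slope"]] * as.numeric(a %*% e$mean_direction)
    1 / (1 + exp(-z))
  }, numeric(nrow(a)))
  matrix(scores, nrow = nrow(a))
}

#' TCAV score of a concept for a class
#'
#' The fraction of class-k samples whose directional derivative — the
#' gradient of the class-k logit with respect to the layer activation,
#' dotted with the concept direction — is strictly positive. Samples with an
#' exactly zero derivative therefore count against the score.
#'
#' @param model A `victim_model`.
#' @param layer Activation layer name.
#' @param cav A `cav`/`cav_ensemble` or a plain direction vector.
#' @param class_samples Image batch (H x W x 3 x N) of class-k samples.
#' @param class_index 1-based class index k.
#' @return Fraction in [0, 1].
#' @export
tcav_score <- function(model, layer, cav, class_samples, class_index) {
  class_samples <- .as_batch(class_samples)
  n <- dim(class_samples)[4]
  if (n == 0L) stop("empty sample set")
  v <- if (inherits(cav, "cav_ensemble")) cav$mean_direction else
    if (inherits(cav, "cav")) cav$direction else as.numeric(cav)
  d <- directional_derivatives(model, layer, v, class_samples, class_index)
  mean(d > 0)
}

#' Directional derivatives of a class score along a concept direction
#'
#' @inheritParams tcav_score
#' @param v Concept direction vector in activation space.
#' @return Numeric vector of per-sample directional derivatives
#'   S(x) = grad_a logit_k(x) . v.
#' @export
directional_derivatives <- function(model, layer, v, class_samples,
                                    class_index) {
  class_samples <- .as_batch(class_samples)
  n <- dim(class_samples)[4]
  nc <- model$arch$num_classes
  if (class_index < 1L || class_index > nc) stop("class_index out of range")
  dlog <- matrix(0, nc, n)
  dlog[class_index, ] <- 1
  g <- .layer_output_gradient(model, class_samples, dlog, layer)
  if (!is.matrix(g)) g <- matrix(g, ncol = n)
  as.numeric(crossprod(g, v))
}
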