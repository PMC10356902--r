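# Per-sample attack features and metric-based membership inference.

#' Extract attack features for a set of samples
#'
#' Computes, per sample, the ingredients of both metric- and classifier-based
#' membership inference attacks: the prediction vector and its derived
#' scalars (cross-entropy loss against the true label, maximum confidence,
#' prediction entropy with natural logarithm, population variance of the
#' prediction entries), and — when requested — saliency and occlusion
#' attribution maps, g-/p-CLM sets over all concepts, and the concept
#' prediction vector.
#'
#' @param model A `victim_model`.
#' @param samples List of `labeled_image` (labels are used for the loss).
#' @param ensembles List of `cav_ensemble` (required for the concept-based
#'   feature groups).
#' @param which Character subset of
#'   `c("prediction", "saliency", "occlusion", "gclm", "pclm", "concept")`.
#' @param window,stride Occlusion / p-CLM parameters.
#' @param progress Print a dot every 100 samples.
#' @return A `sample_features` object: list with `prediction` (N x c),
#'   `loss`, `max_confidence`, `entropy`, `variance` (length-N vectors),
#'   optional `saliency` / `occlusion` (N x H*W matrices), `gclm` / `pclm`
#'   (N x K*H*W matrices), `concept` (N x K), and `ids`.
#' @export
extract_features <- function(model, samples, ensembles = NULL,
                             which = c("prediction"), window = 15L,
                             stride = 8L, progress = FALSE) {
  known <- c("prediction", "saliency", "occlusion", "gclm", "pclm", "concept")
  if (!all(which %in% known)) {
    stop("unknown feature group(s): ", paste(setdiff(which, known), collapse = ", "))
  }
  if (any(c("gclm", "pclm", "concept") %in% which) && is.null(ensembles)) {
    stop("concept-based features need CAV ensembles")
  }
  arr <- as_image_array(samples)
  n <- length(arr$y)
  nc <- model$arch$num_classes
  S <- dim(arr$x)[1]
  out <- list(ids = arr$ids, membership = NULL)

  pred <- matrix(0, n, nc)
  for (s in seq(1, n, by = 256L)) {
    e <- min(s + 255L, n)
    pred[s:e, ] <- predict_proba(model, arr$x[, , , s:e, drop = FALSE])
  }
  out$prediction <- pred
  out$loss <- -log(pmax(pred[cbind(seq_len(n), arr$y + 1L)], 1e-12))
  out$max_confidence <- apply(pred, 1, max)
  out$entropy <- apply(pred, 1, function(p) -sum(ifelse(p > 0, p * log(p), 0)))
  out$variance <- apply(pred, 1, function(p) mean((p - mean(p))^2))

  if ("concept" %in% which) {
    cp <- matrix(0, n, length(ensembles))
    for (s in seq(1, n, by = 256L)) {
      e <- min(s + 255L, n)
      cp[s:e, ] <- concept_predictions(model, arr$x[, , , s:e, drop = FALSE],
                                       ensembles)
    }
    out$concept <- cp
  }
  targets <- max.col(pred)   # attribution target: the predicted class
  if ("saliency" %in% which) {
    out$saliency <- .saliency_batch(model, arr$x, targets)
    if (progress) cat("s")
  }
  if ("occlusion" %in% which) {
    out$occlusion <- .occlusion_batch(model, arr$x, targets, window, stride)
    if (progress) cat("o")
  }
  if ("gclm" %in% which) {
    out$gclm <- .gclm_batch(model, arr$x, ensembles)
    if (progress) cat("g")
  }
  if ("pclm" %in% which) {
    out$pclm <- .pclm_batch(model, arr$x, ensembles, window, stride)
    if (progress) cat("p")
  }
  if (progress) cat("\n")
  structure(out, class = "sample_features")
}

#' Metric-based membership inference AUC
#'
#' Ranks samples by a scalar score and reports the probability that a random
#' member outranks a random non-member (ties count one half), in percent.
#' The orientation is NOT auto-flipped: each metric is fed with a fixed,
#' documented polarity (see [metric_attack_suite()]), so an uninformative or
#' reversed metric can legitimately score below 50%.
#'
#' @param scores Per-sample scalar scores.
#' @param membership Logical or 0/1 vector (TRUE/1 = member).
#' @return AUC in percent.
#' @export
metric_attack_auc <- function(scores, membership) {
  membership <- as.logical(membership)
  m <- sum(membership); nn <- sum(!membership)
  if (m == 0L || nn == 0L) stop("need both members and non-members")
  if (length(scores) != length(membership)) stop("length mismatch")
  r <- rank(scores)                      # average ranks give ties 1/2 credit
  100 * (sum(r[membership]) - m * (m + 1) / 2) / (m * nn)
}

#' All metric-based attacks on a feature set
#'
#' Fixed polarities (members are expected to have): lower loss, higher
#' maximum confidence, lower entropy; prediction variance is used raw with
#' higher-as-member (a peaked prediction has higher entry variance), and the
#' per-sample variances of attribution maps and CLM sets are used raw.
#'
#' @param features A `sample_features` with `membership` set, or a list of
#'   two `sample_features` (members, non-members).
#' @param membership Logical vector when `features` is a single object.
#' @return data.frame with columns `metric`, `auc`.
#' @export
metric_attack_suite <- function(features, membership = NULL) {
  f <- features
  if (is.null(membership)) membership <- f$membership
  if (is.null(membership)) stop("membership bits are required")
  rows <- list(
    c(metric = "loss", auc = metric_attack_auc(-f$loss, membership)),
    c(metric = "max_confidence",
      auc = metric_attack_auc(f$max_confidence, membership)),
    c(metric = "entropy", auc = metric_attack_auc(-f$entropy, membership)),
    c(metric = "prediction_variance",
      auc = metric_attack_auc(f$variance, membership)))
  mapvar <- function(m) apply(m, 1, stats::var)
  if (!is.null(f$saliency)) {
    rows[[length(rows) + 1L]] <- c(metric = "saliency_map_variance",
      auc = metric_attack_auc(mapvar(f$saliency), membership))
  }
  if (!is.null(f$occlusion)) {
    rows[[length(rows) + 1L]] <- c(metric = "occlusion_map_variance",
      auc = metric_attack_auc(mapvar(f$occlusion), membership))
  }
  if (!is.null(f$gclm)) {
    rows[[length(rows) + 1L]] <- c(metric = "gclm_set_variance",
      auc = metric_attack_auc(mapvar(f$gclm), membership))
  }
  if (!is.null(f$pclm)) {
    rows[[length(rows) + 1L]] <- c(metric = "pclm_set_variance",
      auc = metric_attack_auc(mapvar(f$pclm), membership))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  df$auc <- as.numeric(df$auc)
  df
}

#' Concatenate member and non-member feature sets
#'
#' @param members,nonmembers `sample_features` objects with identical groups.
#' @return One `sample_features` with a `membership` logical vector.
#' @export
bind_features <- function(members, nonmembers) {
  groups <- c("prediction", "loss", "max_confidence", "entropy", "variance",
              "saliency", "occlusion", "gclm", "pclm", "concept")
  out <- list(ids = c(members$ids, nonmembers$ids))
  for (g in groups) {
    a <- members[[g]]; b <- nonmembers[[g]]
    if (is.null(a) != is.null(b)) stop("feature group mismatch: ", g)
    if (is.null(a)) next
    out[[g]] <- if (is.matrix(a)) rbind(a, b) else c(a, b)
  }
  out$membership <- rep(c(TRUE, FALSE), c(length(members$ids),
                                          length(nonmembers$ids)))
  structure(out, class = "sample_features")
}
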