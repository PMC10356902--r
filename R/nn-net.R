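# Network assembly, forward/backward drivers and parameter-tree utilities.

#' Victim architecture configuration
#'
#' Both families use group normalization exclusively (no batch norm anywhere,
#' so the same architectures can be trained with per-sample DP-SGD) and end
#' in global average pooling followed by a linear head. Named block layers
#' (`block1..block3`, `gap`, `fc`) are enumerable for activation extraction.
#'
#' @param family `"small_cnn"` (3 strided conv blocks) or
#'   `"resnet_groupnorm"` (strided stem + 3 residual stages).
#' @param width Channels of the first block; later blocks double it.
#' @param depth Residual blocks per stage (resnet family only).
#' @param num_classes Output dimension.
#' @param groups Group-norm groups.
#' @return An `arch_config`.
#' @export
arch_config <- function(family = c("small_cnn", "resnet_groupnorm"),
                        width = NULL, depth = 1L, num_classes = 2L,
                        groups = 4L) {
  family <- match.arg(family)
  if (is.null(width)) width <- 12L
  structure(list(family = family, width = as.integer(width),
                 depth = as.integer(depth), num_classes = as.integer(num_classes),
                 groups = as.integer(groups)),
            class = "arch_config")
}

.build_layers <- function(arch, seed) {
  if (!arch$family %in% c("small_cnn", "resnet_groupnorm")) {
    stop("unknown architecture family: ", arch$family)
  }
  w <- arch$width; g <- arch$groups; nc <- arch$num_classes
  if (arch$family == "small_cnn") {
    layers <- list(
      nn_conv(3L, w, 3L, 2L, 1L, "conv1", seed),
      nn_groupnorm(w, g, "gn1"),
      nn_relu("block1"),
      nn_conv(w, 2L * w, 3L, 2L, 1L, "conv2", seed + 10L),
      nn_groupnorm(2L * w, g, "gn2"),
      nn_relu("block2"),
      nn_conv(2L * w, 4L * w, 3L, 2L, 1L, "conv3", seed + 20L),
      nn_groupnorm(4L * w, g, "gn3"),
      nn_relu("block3"),
      nn_gap("gap"),
      nn_linear(4L * w, nc, "fc", seed + 30L))
  } else {
    layers <- list(
      nn_conv(3L, w, 3L, 2L, 1L, "stem.conv", seed),
      nn_groupnorm(w, g, "stem.gn"),
      nn_relu("stem"))
    widths <- c(w, 2L * w, 4L * w)
    strides <- c(2L, 2L, 1L)
    cin <- w
    for (s in 1:3) {
      for (b in seq_len(arch$depth)) {
        nm <- if (b == arch$depth) paste0("block", s) else
          sprintf("stage%d.b%d", s, b)
        layers[[length(layers) + 1L]] <-
          nn_resblock(cin, widths[s], if (b == 1L) strides[s] else 1L,
                      nm, seed + 100L * s + 10L * b)
        cin <- widths[s]
      }
    }
    layers[[length(layers) + 1L]] <- nn_gap("gap")
    layers[[length(layers) + 1L]] <- nn_linear(4L * w, nc, "fc", seed + 999L)
  }
  names(layers) <- vapply(layers, function(l) l$name, "")
  layers
}

#' Build an untrained victim model
#'
#' @param arch An [arch_config()].
#' @param seed Weight-initialization seed.
#' @return A `victim_model` whose forward pass maps an image batch to
#'   `num_classes` logits. Inputs in [0,1] are normalized internally to
#'   (x - 0.5) / 0.25.
#' @export
build_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "arch_config"))
  structure(list(layers = .build_layers(arch, seed), arch = arch,
                 regime = NULL, spent_privacy = NULL, training_log = NULL,
                 init_seed = as.integer(seed)),
            class = "victim_model")
}

#' @export
print.victim_model <- function(x, ...) {
  cat("<victim_model>", x$arch$family, "width", x$arch$width,
      "classes", x$arch$num_classes,
      if (!is.null(x$regime)) paste("| regime:", x$regime) else "| untrained", "\n")
  if (!is.null(x$spent_privacy)) {
    cat(sprintf("  (eps, delta) spent: (%.3f, %g)\n",
                x$spent_privacy$epsilon, x$spent_privacy$delta))
  }
  invisible(x)
}

#' Names of the introspectable layers of a model
#' @param model A `victim_model`.
#' @return Character vector of layer names.
#' @export
layer_names <- function(model) names(model$layers)

# convert (H, W, 3, N) image batches to internal channel-fastest layout,
# applying input normalization
.to_internal <- function(x, normalize = TRUE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x <- aperm(x, c(3, 1, 2, 4))
  if (normalize) x <- (x - 0.5) / 0.25
  x
}

.net_forward <- function(model, xint, keep = FALSE) {
  caches <- if (keep) vector("list", length(model$layers)) else NULL
  outs <- if (keep) vector("list", length(model$layers)) else NULL
  h <- xint
  for (i in seq_along(model$layers)) {
    r <- .layer_fwd(model$layers[[i]], h)
    h <- r$out
    if (keep) { caches[[i]] <- r$cache; outs[[i]] <- h }
  }
  if (keep) { names(outs) <- names(model$layers) }
  list(logits = h, caches = caches, outs = outs)
}

# backward pass. dout is the gradient at the output of layer `from` (the
# logits when `from` is the last layer). Stops after layer `to`; returns the
# gradient at the input of layer `to` (the image gradient when to == 1) in
# `dx`, plus per-layer parameter gradients for the traversed layers.
.net_backward <- function(model, caches, dout, from = length(model$layers),
                          to = 1L, need_dx = TRUE, need_grads = TRUE) {
  grads <- vector("list", length(model$layers))
  for (i in seq(from, to)) {
    last <- (i == to)
    r <- .layer_bwd(model$layers[[i]], dout, caches[[i]],
                    need_dx = need_dx || !last)
    if (need_grads) grads[[i]] <- r$grads
    dout <- r$dx
  }
  names(grads) <- names(model$layers)
  list(dx = dout, grads = grads)
}

.layer_index <- function(model, layer) {
  i <- match(layer, names(model$layers))
  if (is.na(i)) stop("unknown layer: ", layer)
  i
}

#' Class probabilities for a batch of images
#'
#' @param model A `victim_model`.
#' @param x Image batch, H x W x 3 x N array (or a single H x W x 3 image).
#' @return N x num_classes matrix of softmax probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, x) {
  r <- .net_forward(model, .to_internal(x))
  t(.softmax(r$logits))
}

.softmax <- function(logits) {
  z <- logits - rep(apply(logits, 2, max), each = nrow(logits))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(logits))
}

# weighted softmax cross-entropy; y is 0-based labels
.softmax_ce <- function(logits, y, class_weights = NULL) {
  n <- ncol(logits); k <- nrow(logits)
  p <- .softmax(logits)
  iy <- cbind(y + 1L, seq_len(n))
  w <- if (is.null(class_weights)) rep(1, n) else class_weights[y + 1L]
  py <- p[cbind(y + 1L, seq_len(n))]
  loss <- sum(-w * log(pmax(py, 1e-12))) / sum(w)
  d <- p * rep(w, each = k)
  d[iy] <- d[iy] - w
  d <- d / sum(w)
  list(loss = loss, dlogits = d, probs = p)
}

#' Activations of a named layer
#'
#' @param model A `victim_model`.
#' @param x Image batch (H x W x 3 x N).
#' @param layer Layer name (see [layer_names()]); `"gap"` yields the pooled
#'   feature matrix used for concept activation vectors.
#' @return For dense layers an N x F matrix; for spatial layers the raw
#'   (C, H, W, N) activation array.
#' @export
activations_at <- function(model, x, layer) {
  i <- .layer_index(model, layer)
  h <- .to_internal(x)
  for (j in seq_len(i)) h <- .layer_fwd(model$layers[[j]], h)$out
  if (is.matrix(h)) t(h) else h
}

#' Gradient of a class logit with respect to the input image
#'
#' @param model A `victim_model`.
#' @param x Image batch (H x W x 3 x N).
#' @param target_index 1-based class index whose logit is differentiated.
#' @return H x W x 3 x N array of input gradients (chain rule includes the
#'   internal input normalization).
#' @export
input_gradient <- function(model, x, target_index) {
  nc <- model$arch$num_classes
  if (target_index < 1L || target_index > nc) stop("target_index out of range")
  r <- .net_forward(model, .to_internal(x), keep = TRUE)
  n <- ncol(r$logits)
  dlog <- matrix(0, nc, n)
  dlog[target_index, ] <- 1
  b <- .net_backward(model, r$caches, dlog, need_grads = FALSE)
  dx <- b$dx / 0.25           # through the input normalization
  aperm(dx, c(2, 3, 1, 4))
}

# gradient of class logits (combination `dlogits`) w.r.t. the output of a
# named layer; returns the gradient array/matrix at that layer's output
.layer_output_gradient <- function(model, x, dlogits, layer) {
  i <- .layer_index(model, layer)
  L <- length(model$layers)
  if (i == L) stop("layer is the output layer")
  r <- .net_forward(model, .to_internal(x), keep = TRUE)
  b <- .net_backward(model, r$caches, dlogits, from = L, to = i + 1L,
                     need_grads = FALSE)
  b$dx
}

# gradient of a scalar defined at a layer's output w.r.t. the input image:
# backward from layer i down to the input with seed gradient `dact`
.input_gradient_from_layer <- function(model, x, layer, dact) {
  i <- .layer_index(model, layer)
  r <- .net_forward(model, .to_internal(x), keep = TRUE)
  b <- .net_backward(model, r$caches, dact, from = i, to = 1L,
                     need_grads = FALSE)
  aperm(b$dx / 0.25, c(2, 3, 1, 4))
}

# ---- parameter trees --------------------------------------------------------

.par_tree <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "resblock") lapply(l$sub, function(s) s$params) else l$params
  })
}

.set_par_tree <- function(layers, tree) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "resblock") {
      for (nm in names(layers[[i]]$sub)) layers[[i]]$sub[[nm]]$params <- tree[[i]][[nm]]
    } else {
      layers[[i]]$params <- tree[[i]]
    }
  }
  layers
}

.tree_map2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- .tree_map2(a[[nm]], b[[nm]], f)
  out
}

.tree_map <- function(a, f) {
  if (is.numeric(a)) return(f(a))
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- .tree_map(a[[nm]], f)
  out
}

.tree_sumsq <- function(a) {
  if (is.numeric(a)) return(sum(a * a))
  s <- 0
  for (el in a) s <- s + .tree_sumsq(el)
  s
}

.tree_zero_like <- function(a) .tree_map(a, function(x) x * 0)

# grads from .net_backward have empty entries for parameterless layers; make
# them a full tree aligned with .par_tree
.grads_as_tree <- function(layers, grads) {
  out <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "resblock") {
      g <- grads[[i]]
      full <- lapply(layers[[i]]$sub, function(s) .tree_zero_like(s$params))
      for (nm in names(g)) full[[nm]] <- g[[nm]]
      out[[i]] <- full
    } else if (length(layers[[i]]$params)) {
      out[[i]] <- if (is.null(grads[[i]]) || !length(grads[[i]]))
        .tree_zero_like(layers[[i]]$params) else grads[[i]]
    } else {
      out[[i]] <- list()
    }
  }
  out
}
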