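# Attribution maps: gradient-based saliency and perturbation-based occlusion.

#' Saliency attribution map
#'
#' The relevance of each input pixel is the gradient of the target class
#' logit with respect to the input; the per-pixel value is the channel-wise
#' maximum of the absolute gradient (a fixed convention so downstream
#' attacks see one scalar per pixel).
#'
#' @param model A `victim_model`.
#' @param image H x W x 3 array in [0,1].
#' @param target_index 1-based class index.
#' @return An `attribution_map`: list with `values` (H x W, non-negative),
#'   `method`, `target_index`.
#' @export
saliency <- function(model, image, target_index) {
  g <- input_gradient(model, .as_batch(image), target_index)
  v <- apply(abs(g[, , , 1, drop = FALSE]), c(1, 2), max)
  structure(list(values = v, method = "saliency",
                 target_index = target_index),
            class = "attribution_map")
}

.as_batch <- function(image) {
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  image
}

# sliding-window positions covering the full image (top-left corners);
# the final position is clamped so that every pixel is covered
.window_starts <- function(side, window, stride) {
  if (stride <= 0) stop("stride must be > 0")
  if (window > side) stop("window larger than image side")
  s <- seq(1L, max(side - window + 1L, 1L), by = stride)
  if (s[length(s)] + window - 1L < side) s <- c(s, side - window + 1L)
  as.integer(s)
}

# generic perturbation-map driver: `perturb(img, rs, cs)` returns the
# perturbed image; `score(batch)` maps an (H,W,3,N) batch to N scalars.
.perturbation_map <- function(image, window, stride, perturb, score,
                              batch = 64L) {
  d <- dim(image)
  rs <- .window_starts(d[1], window, stride)
  cs <- .window_starts(d[2], window, stride)
  pos <- expand.grid(r = rs, c = cs)
  clean <- score(.as_batch(image))
  vals <- matrix(0, d[1], d[2])
  cover <- matrix(0, d[1], d[2])
  np <- nrow(pos)
  scores <- numeric(np)
  for (s in seq(1, np, by = batch)) {
    e <- min(s + batch - 1L, np)
    xb <- array(0, c(d[1], d[2], 3, e - s + 1L))
    for (j in s:e) {
      xb[, , , j - s + 1L] <- perturb(image, pos$r[j]:(pos$r[j] + window - 1L),
                                      pos$c[j]:(pos$c[j] + window - 1L))
    }
    scores[s:e] <- score(xb)
  }
  for (j in seq_len(np)) {
    ri <- pos$r[j]:(pos$r[j] + window - 1L)
    ci <- pos$c[j]:(pos$c[j] + window - 1L)
    vals[ri, ci] <- vals[ri, ci] + (clean - scores[j])
    cover[ri, ci] <- cover[ri, ci] + 1
  }
  vals / pmax(cover, 1)
}

#' Occlusion attribution map
#'
#' Slides a square window over the image, replaces its content with the mean
#' pixel value of the image, and records the drop in the target class score.
#' Overlapping window contributions are averaged per pixel by coverage
#' count. Positive relevance marks regions whose occlusion lowers the score.
#'
#' @param model A `victim_model`, or a function mapping an (H,W,3,N) batch to
#'   N scalar scores (then `target_index` is ignored for scoring).
#' @param image H x W x 3 array in [0,1].
#' @param target_index 1-based class index (the tracked score is the softmax
#'   probability of this class).
#' @param window,stride Occlusion window side and stride in pixels.
#' @param fill Fill value for the occluded patch; defaults to the image mean.
#' @return An `attribution_map` with signed `values` (H x W).
#' @export
occlusion <- function(model, image, target_index = 1L, window = 15L,
                      stride = 8L, fill = NULL) {
  if (is.function(model)) {
    score <- model
  } else {
    nc <- model$arch$num_classes
    if (target_index < 1L || target_index > nc) stop("target_index out of range")
    score <- function(xb) predict_proba(model, xb)[, target_index]
  }
  if (is.null(fill)) fill <- mean(image)
  perturb <- function(img, ri, ci) { img[ri, ci, ] <- fill; img }
  v <- .perturbation_map(image, as.integer(window), as.integer(stride),
                         perturb, score)
  structure(list(values = v, method = "occlusion",
                 target_index = target_index),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat("<attribution_map>", x$method, "target", x$target_index,
      "range", sprintf("[%.3g, %.3g]", min(x$values), max(x$values)), "\n")
  invisible(x)
}
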