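# Concept localization maps: where on the input a concept is expressed.

# separable Gaussian blur via row/column kernel matrices (edge-renormalized)
.blur_kernel <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-d^2 / (2 * sigma^2))
  k[abs(d) > ceiling(3 * sigma)] <- 0
  k / rowSums(k)
}

.gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  d <- dim(image)
  kh <- .blur_kernel(d[1], sigma)
  kw <- .blur_kernel(d[2], sigma)
  out <- image
  for (ch in seq_len(d[3])) out[, , ch] <- kh %*% image[, , ch] %*% t(kw)
  out
}

#' Gradient-based concept localization map (g-CLM)
#'
#' Saliency applied to the concept score: the gradient of the projection of
#' the layer activation on the concept's mean direction with respect to the
#' input, per-pixel channel-maximum of the absolute value. Positive relevance
#' supports concept presence.
#'
#' @param model A `victim_model`.
#' @param image H x W x 3 array.
#' @param ensemble A `cav_ensemble` (trained at a differentiable layer).
#' @return A `clm`: list with `values` (H x W), `variant = "g"`,
#'   `concept_id`.
#' @export
g_clm <- function(model, image, ensemble) {
  x <- .as_batch(image)
  a <- activations_at(model, x, ensemble$layer)
  if (!is.matrix(a)) stop("g-CLM requires a feature-vector layer")
  dact <- matrix(ensemble$mean_direction, ncol(a), nrow(a))
  g <- .input_gradient_from_layer(model, x, ensemble$layer, dact)
  v <- apply(abs(g[, , , 1, drop = FALSE]), c(1, 2), max)
  structure(list(values = v, variant = "g", concept_id = ensemble$concept_id),
            class = "clm")
}

#' Perturbation-based concept localization map (p-CLM)
#'
#' Occlusion-style relevance of the calibrated concept score: each window is
#' replaced by a blend of the Gaussian-blurred image and the original, with
#' a circular Gaussian weight that blurs fully at the window center and
#' decays toward the window edge. Relevance is (clean concept score -
#' perturbed concept score), averaged per pixel by coverage.
#'
#' @inheritParams g_clm
#' @param window,stride Window side and stride in pixels (defaults 15 / 8).
#' @param blur_sigma Blur standard deviation; defaults to `window / 4`
#'   (0 makes the perturbation a no-op and the map identically zero).
#' @return A `clm` with `variant = "p"`.
#' @export
p_clm <- function(model, image, ensemble, window = 15L, stride = 8L,
                  blur_sigma = NULL) {
  window <- as.integer(window); stride <- as.integer(stride)
  if (is.null(blur_sigma)) blur_sigma <- window / 4
  if (blur_sigma <= 0) {
    # identity blur: the perturbation is a no-op, the map exactly zero
    return(structure(list(values = matrix(0, dim(image)[1], dim(image)[2]),
                          variant = "p", concept_id = ensemble$concept_id),
                     class = "clm"))
  }
  blurred <- .gaussian_blur(image, blur_sigma)
  ctr <- (window + 1) / 2
  dmat <- sqrt(outer((seq_len(window) - ctr)^2,
                     (seq_len(window) - ctr)^2, "+"))
  wgt <- exp(-dmat^2 / (2 * (window / 4)^2))  # 1 at center, ~0 at the rim
  perturb <- function(img, ri, ci) {
    for (ch in 1:3) {
      img[ri, ci, ch] <- wgt * blurred[ri, ci, ch] +
        (1 - wgt) * img[ri, ci, ch]
    }
    img
  }
  score <- function(xb) concept_predictions(model, xb, list(ensemble))[, 1]
  v <- .perturbation_map(image, window, stride, perturb, score)
  structure(list(values = v, variant = "p", concept_id = ensemble$concept_id),
            class = "clm")
}

#' @export
print.clm <- function(x, ...) {
  cat(sprintf("<clm> %s-CLM concept %d range [%.3g, %.3g]\n", x$variant,
              x$concept_id, min(x$values), max(x$values)))
  invisible(x)
}

#' Serialize attribution/CLM maps
#'
#' Maps are stored as portable float arrays (RDS) with an optional PNG
#' preview (min-max normalized).
#'
#' @param map An `attribution_map` or `clm`.
#' @param path Basename without extension.
#' @param preview Also write `<path>.png`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, preview = FALSE) {
  saveRDS(map, paste0(path, ".rds"))
  if (preview) {
    v <- map$values
    rng <- range(v)
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
    png::writePNG(v, paste0(path, ".png"))
  }
  invisible(path)
}
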