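# Rasterization of the synthetic concept images.
#
# Coordinate convention: row-major with origin at the top-left pixel; a
# pixel's x coordinate is its column index, its y coordinate its row index
# (both 1-based). Images are H x W x 3 arrays of intensities in [0, 1].

# membership tests; xs, ys are numeric vectors over the pixel grid
.rot_uv <- function(xs, ys, cx, cy, theta) {
  dx <- xs - cx; dy <- ys - cy
  list(u = dx * cos(theta) + dy * sin(theta),
       v = -dx * sin(theta) + dy * cos(theta))
}

.shape_ellipse <- function(xs, ys, cx, cy, r, theta, ratio) {
  uv <- .rot_uv(xs, ys, cx, cy, theta)
  (uv$u / r)^2 + (uv$v / (r * ratio))^2 <= 1
}

.shape_rect <- function(xs, ys, cx, cy, a, b, theta) {
  uv <- .rot_uv(xs, ys, cx, cy, theta)
  abs(uv$u) <= a & abs(uv$v) <= b
}

.shape_triangle <- function(xs, ys, cx, cy, r, theta) {
  ang <- theta + c(0, 2, 4) * pi / 3
  vx <- cx + r * cos(ang); vy <- cy + r * sin(ang)
  inside <- rep(TRUE, length(xs))
  for (k in 1:3) {
    k2 <- if (k == 3) 1L else k + 1L
    ex <- vx[k2] - vx[k]; ey <- vy[k2] - vy[k]
    # vertices are counter-clockwise in (x, y-down) for increasing angle
    side <- ex * (ys - vy[k]) - ey * (xs - vx[k])
    inside <- inside & side >= 0
  }
  inside
}

.shape_star <- function(xs, ys, cx, cy, r, theta) {
  # hexagram: two overlaid equilateral triangles
  .shape_triangle(xs, ys, cx, cy, r, theta) |
    .shape_triangle(xs, ys, cx, cy, r, theta + pi / 3)
}

.shape_cross <- function(xs, ys, cx, cy, r, theta) {
  .shape_rect(xs, ys, cx, cy, r, 0.3 * r, theta) |
    .shape_rect(xs, ys, cx, cy, r, 0.3 * r, theta + pi / 2)
}

.shape_ring <- function(xs, ys, cx, cy, r, theta) {
  d2 <- (xs - cx)^2 + (ys - cy)^2
  d2 <= r^2 & d2 >= (0.55 * r)^2
}

.shape_dots <- function(xs, ys, cx, cy, r, offs_x, offs_y) {
  rd <- 0.3 * r
  m <- rep(FALSE, length(xs))
  for (k in seq_along(offs_x)) {
    m <- m | ((xs - (cx + offs_x[k] * r))^2 +
              (ys - (cy + offs_y[k] * r))^2 <= rd^2)
  }
  m
}

.shape_stripe <- function(xs, ys, cx, cy, r, theta) {
  # long thin bar: length ~4 radii, width ~0.5 radius
  .shape_rect(xs, ys, cx, cy, 2.0 * r, 0.25 * r, theta)
}

# draws one instance mask; consumes a fixed number of random draws per family
.draw_instance <- function(family, xs, ys, cx, cy, r) {
  theta <- stats::runif(1, 0, 2 * pi)
  switch(family,
    ellipse = .shape_ellipse(xs, ys, cx, cy, r, theta, stats::runif(1, 0.5, 0.8)),
    triangle = .shape_triangle(xs, ys, cx, cy, 1.2 * r, theta),
    star = .shape_star(xs, ys, cx, cy, 1.2 * r, theta),
    rectangle = .shape_rect(xs, ys, cx, cy, r, r * stats::runif(1, 0.45, 0.7), theta),
    cross = .shape_cross(xs, ys, cx, cy, 1.1 * r, theta),
    ring = .shape_ring(xs, ys, cx, cy, 1.1 * r, theta),
    dot_cluster = .shape_dots(xs, ys, cx, cy, 1.3 * r,
                              stats::runif(4, -1, 1), stats::runif(4, -1, 1)),
    stripe = .shape_stripe(xs, ys, cx, cy, r, theta),
    stop("unknown family ", family))
}

.sample_presence <- function(config) {
  K <- config$n_concepts
  repeat {
    presence <- as.integer(stats::runif(K) < config$presence_prob)
    lab <- config$class_rule(presence)
    if (!is.na(lab)) return(list(presence = presence, label = as.integer(lab)))
  }
}

#' Generate one labeled synthetic image
#'
#' Draws a lesion-like base blob on a skin-toned textured background, samples
#' a valid concept-presence vector (resampling vectors the class rule marks
#' invalid), renders the present concept shapes inside the blob (instances may
#' overlap and occlude each other), and records each concept's own footprint
#' as a ground-truth mask even where it is overpainted. Class-discriminative
#' evidence is sparse: the discriminative shapes cover a small fraction of
#' the blob.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for this image; identical `(config, seed)` pairs
#'   produce bit-identical images. The shifted variant of a config consumes
#'   the identical random stream, so paired comparisons at equal seeds isolate
#'   the effect of the shift.
#' @param sample_id Optional id string stored on the image.
#' @return A `labeled_image`: list with `pixels` (H x W x 3 array in [0,1]),
#'   `class_label`, `concept_presence`, `concept_mask_idx` (per concept the
#'   column-major pixel indices of its mask), `sample_id`, `image_size`.
#' @export
generate_image <- function(config, seed, sample_id = paste0("s", seed)) {
  stopifnot(inherits(config, "generator_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))

  S <- config$image_size
  xs <- rep(seq_len(S), each = S)    # column (x) per column-major cell
  ys <- rep(seq_len(S), times = S)   # row (y)
  npx <- S * S
  sh <- config$shift

  # background: skin tone + low-frequency texture
  bg <- stats::runif(3, c(0.90, 0.76, 0.68), c(0.96, 0.84, 0.76))
  tex_amp <- 0.02 + sh$background_texture_delta
  tex_freq <- stats::runif(2, 1.5, 3.5) / S
  tex_phase <- stats::runif(1, 0, 2 * pi)
  tex <- sin(2 * pi * (tex_freq[1] * xs + tex_freq[2] * ys) + tex_phase)
  px <- matrix(0, npx, 3)
  for (ch in 1:3) px[, ch] <- bg[ch] + tex_amp * tex

  # base blob: ellipsoidal with low-frequency boundary modulation
  bs <- config$base_shape
  cx <- S * (0.5 + stats::runif(1, -0.05, 0.05))
  cy <- S * (0.5 + stats::runif(1, -0.05, 0.05))
  R <- S * stats::runif(1, bs$radius_range[1], bs$radius_range[2])
  mod_amp <- c(0.08, 0.05, 0.03)
  mod_k <- c(2, 3, 5)
  mod_phase <- stats::runif(3, 0, 2 * pi)
  dx <- xs - cx; dy <- ys - cy
  phi <- atan2(dy, dx)
  rb <- R * (1 + mod_amp[1] * sin(mod_k[1] * phi + mod_phase[1]) +
                 mod_amp[2] * sin(mod_k[2] * phi + mod_phase[2]) +
                 mod_amp[3] * sin(mod_k[3] * phi + mod_phase[3]))
  blob <- (dx * dx + dy * dy) <= rb * rb
  blob_col <- stats::runif(3, bs$color_low, bs$color_high)
  for (ch in 1:3) px[blob, ch] <- blob_col[ch]

  # concept sampling and rendering
  ps <- .sample_presence(config)
  presence <- ps$presence
  K <- config$n_concepts
  scale_mul <- 1 + sh$shape_scale_delta
  masks <- vector("list", K)
  paint <- list()
  for (k in seq_len(K)) {
    masks[[k]] <- integer(0)
    if (presence[k] != 1L) next
    cs <- config$concepts[[k]]
    n_inst <- if (cs$count_range[1] == cs$count_range[2]) cs$count_range[1] else
      sample(cs$count_range[1]:cs$count_range[2], 1)
    acc <- rep(FALSE, npx)
    for (j in seq_len(n_inst)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * 0.55 * R
      ccx <- cx + rad * cos(ang); ccy <- cy + rad * sin(ang)
      r <- scale_mul * S * stats::runif(1, cs$size_range[1], cs$size_range[2])
      col <- stats::runif(3, cs$color_range[, 1], cs$color_range[, 2])
      m <- .draw_instance(cs$shape_family, xs, ys, ccx, ccy, r) & blob
      if (!any(m)) { # degenerate raster: force the (in-blob) center pixel
        ci <- (round(ccy) - 1) * S + round(ccx)
        ci <- min(max(ci, 1), npx)
        m[ci] <- TRUE
      }
      acc <- acc | m
      paint[[length(paint) + 1L]] <- list(mask = m, col = col)
    }
    masks[[k]] <- which(acc)
  }
  # later shapes composite over earlier ones
  for (p in paint) for (ch in 1:3) px[p$mask, ch] <- p$col[ch]

  # per-image color jitter (draws always consumed so streams stay aligned)
  jit <- stats::rnorm(3) * sh$color_jitter_delta
  # pixel noise
  sigma <- config$noise_sigma + sh$noise_sigma_delta
  noise <- stats::rnorm(npx * 3) * sigma
  px <- px + rep(jit, each = npx) + matrix(noise, npx, 3)
  px[px < 0] <- 0; px[px > 1] <- 1

  names(presence) <- vapply(config$concepts, function(cc) cc$shape_family, "")
  structure(list(pixels = array(px, c(S, S, 3)),
                 class_label = ps$label,
                 concept_presence = presence,
                 concept_mask_idx = masks,
                 sample_id = sample_id,
                 image_size = S),
            class = "labeled_image")
}

#' Binary mask of one concept on a labeled image
#'
#' @param img A `labeled_image`.
#' @param k Concept index (1-based).
#' @return H x W 0/1 matrix.
#' @export
concept_mask <- function(img, k) {
  S <- img$image_size
  m <- matrix(0, S, S)
  m[img$concept_mask_idx[[k]]] <- 1
  m
}

#' @export
print.labeled_image <- function(x, ...) {
  cat("<labeled_image>", x$sample_id, paste0(x$image_size, "px"),
      "class", x$class_label, "presence",
      paste(x$concept_presence, collapse = ""), "\n")
  invisible(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# deterministic per-stage / per-item seed fan-out, kept below 2^31
.fan_seed <- function(seed, stage, item = 0L) {
  (as.double(seed) * 48271 + stage * 16807 + item * 69621) %% 2147483563
}
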