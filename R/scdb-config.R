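#' Concept specification
#'
#' Describes one geometric concept family that the synthetic benchmark can
#' draw on the lesion-like base blob. Sizes are expressed as fractions of the
#' image side so that configurations are resolution independent.
#'
#' @param concept_id Integer id, unique within a generator configuration.
#' @param shape_family One of `"ellipse"`, `"triangle"`, `"star"`,
#'   `"rectangle"`, `"cross"`, `"ring"`, `"dot_cluster"`, `"stripe"`.
#' @param size_range Length-2 numeric, shape radius as a fraction of the image
#'   side (must lie in (0, 0.5]).
#' @param color_range 3x2 matrix of per-channel RGB bounds in [0, 1]
#'   (rows R, G, B; columns low, high).
#' @param count_range Length-2 integer, instances drawn per image when the
#'   concept is present (minimum >= 1).
#' @return An object of class `concept_spec`.
#' @export
concept_spec <- function(concept_id, shape_family, size_range, color_range,
                         count_range = c(1L, 1L)) {
  families <- c("ellipse", "triangle", "star", "rectangle", "cross",
                "ring", "dot_cluster", "stripe")
  if (!shape_family %in% families) {
    stop("unknown shape_family: ", shape_family)
  }
  if (length(size_range) != 2L || any(size_range <= 0) || any(size_range > 0.5) ||
      size_range[1] > size_range[2]) {
    stop("size_range must be an increasing interval within (0, 0.5]")
  }
  color_range <- as.matrix(color_range)
  if (!all(dim(color_range) == c(3L, 2L)) || any(color_range < 0) ||
      any(color_range > 1)) {
    stop("color_range must be a 3x2 matrix of RGB bounds in [0, 1]")
  }
  count_range <- as.integer(count_range)
  if (length(count_range) != 2L || count_range[1] < 1L ||
      count_range[1] > count_range[2]) {
    stop("count_range must be an increasing integer interval with min >= 1")
  }
  structure(list(concept_id = as.integer(concept_id),
                 shape_family = shape_family,
                 size_range = as.numeric(size_range),
                 color_range = color_range,
                 count_range = count_range),
            class = "concept_spec")
}

.default_concepts <- function() {
  col <- function(lo, hi) cbind(low = lo, high = hi)
  list(
    concept_spec(1L, "ellipse",     c(0.07, 0.11), col(c(0.20, 0.30, 0.60), c(0.40, 0.50, 0.80)), c(1L, 2L)),
    concept_spec(2L, "triangle",    c(0.08, 0.13), col(c(0.70, 0.10, 0.10), c(0.90, 0.30, 0.30)), c(1L, 2L)),
    concept_spec(3L, "star",        c(0.08, 0.13), col(c(0.85, 0.75, 0.10), c(1.00, 0.95, 0.30)), c(1L, 2L)),
    concept_spec(4L, "rectangle",   c(0.08, 0.13), col(c(0.10, 0.50, 0.10), c(0.30, 0.70, 0.30)), c(1L, 2L)),
    concept_spec(5L, "cross",       c(0.08, 0.13), col(c(0.50, 0.10, 0.50), c(0.70, 0.30, 0.70)), c(1L, 2L)),
    concept_spec(6L, "ring",        c(0.08, 0.13), col(c(0.10, 0.65, 0.65), c(0.30, 0.90, 0.90)), c(1L, 2L)),
    concept_spec(7L, "dot_cluster", c(0.07, 0.11), col(c(0.85, 0.45, 0.05), c(1.00, 0.65, 0.20)), c(1L, 2L)),
    concept_spec(8L, "stripe",      c(0.08, 0.13), col(c(0.30, 0.18, 0.08), c(0.50, 0.38, 0.28)), c(1L, 1L))
  )
}

#' Default class rule of the synthetic benchmark
#'
#' Class 1 evidence is (star AND triangle) OR cross; class 0 evidence is
#' (ring AND rectangle) OR stripe. A presence vector is valid when exactly one
#' of the two evidence branches holds; the generator resamples invalid
#' vectors. Ellipse and dot-cluster are distractors that appear in either
#' class. The rule is therefore total and deterministic over the valid
#' presence vectors, and the class is computable with 100% accuracy from the
#' true presence bits.
#'
#' @param presence Binary vector of length 8 in the default concept order
#'   (ellipse, triangle, star, rectangle, cross, ring, dot_cluster, stripe).
#' @return 0 or 1, or `NA_integer_` for an invalid (ambiguous) vector.
#' @export
default_class_rule <- function(presence) {
  p <- as.logical(presence)
  c1 <- (p[3] && p[2]) || p[5]   # (star & triangle) | cross
  c0 <- (p[6] && p[4]) || p[8]   # (ring & rectangle) | stripe
  if (c1 && !c0) return(1L)
  if (c0 && !c1) return(0L)
  NA_integer_
}

#' Distribution-shift configuration
#'
#' Parameterizes the shifted variant of the generator used to emulate a
#' deployment population that differs slightly from the training
#' distribution. All deltas are non-negative; an all-zero shift reproduces
#' the base distribution bit for bit (the shifted generator consumes the same
#' random draws).
#'
#' @param background_texture_delta Extra amplitude of the low-frequency
#'   background texture (intensity units).
#' @param color_jitter_delta Standard deviation of a per-image global RGB
#'   offset (intensity units).
#' @param shape_scale_delta Multiplicative enlargement of all shape sizes
#'   (`1 + delta` scale factor).
#' @param noise_sigma_delta Additive increase of the pixel noise standard
#'   deviation.
#' @return An object of class `shift_config`.
#' @export
shift_config <- function(background_texture_delta = 0,
                         color_jitter_delta = 0,
                         shape_scale_delta = 0,
                         noise_sigma_delta = 0) {
  vals <- c(background_texture_delta, color_jitter_delta,
            shape_scale_delta, noise_sigma_delta)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("shift deltas must be finite and >= 0")
  }
  structure(list(background_texture_delta = background_texture_delta,
                 color_jitter_delta = color_jitter_delta,
                 shape_scale_delta = shape_scale_delta,
                 noise_sigma_delta = noise_sigma_delta),
            class = "shift_config")
}

#' Default shift of the suboptimal deployment scenario
#'
#' @return A `shift_config` with color jitter 0.15, shape scale 0.2 and noise
#'   sigma 0.02 — a mild shift under which a baseline classifier keeps most of
#'   its accuracy while the distributions remain distinguishable.
#' @export
default_shift <- function() {
  shift_config(background_texture_delta = 0.02,
               color_jitter_delta = 0.15,
               shape_scale_delta = 0.2,
               noise_sigma_delta = 0.02)
}

#' Generator configuration for the synthetic concept benchmark
#'
#' @param image_size Side of the square image in pixels.
#' @param concepts List of [concept_spec()] objects (ids must be unique).
#' @param class_rule Function mapping a presence vector to 0/1 (or NA for
#'   invalid vectors, which the generator resamples).
#' @param class_rule_id Short string identifying the rule in provenance files.
#' @param split_sizes Named integer vector `(train, val, test, concept)`.
#' @param presence_prob Per-concept Bernoulli presence probability.
#' @param base_shape List with blob parameters (`radius_range` as fraction of
#'   the image side, `color_low`/`color_high` RGB bounds).
#' @param noise_sigma Base pixel-noise standard deviation.
#' @param shift A [shift_config()]; zero by default.
#' @param seed Integer seed; together with the rest of the configuration it
#'   determines the dataset bit for bit.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(image_size = 128L,
                             concepts = .default_concepts(),
                             class_rule = default_class_rule,
                             class_rule_id = "default-v1",
                             split_sizes = c(train = 4800L, val = 1200L,
                                             test = 1500L, concept = 6000L),
                             presence_prob = 0.5,
                             base_shape = list(radius_range = c(0.32, 0.40),
                                               color_low = c(0.62, 0.42, 0.34),
                                               color_high = c(0.78, 0.58, 0.48)),
                             noise_sigma = 0.01,
                             shift = shift_config(),
                             seed = 0L) {
  image_size <- as.integer(image_size)
  if (image_size < 16L) stop("image_size must be >= 16")
  ids <- vapply(concepts, function(cs) cs$concept_id, integer(1))
  if (anyDuplicated(ids)) stop("concept_ids must be unique")
  if (length(concepts) < 6L) stop("need at least 6 concepts")
  split_sizes <- as.integer(split_sizes)
  names(split_sizes) <- c("train", "val", "test", "concept")
  if (any(split_sizes <= 0L)) stop("split sizes must be positive")
  if (!is.function(class_rule)) stop("class_rule must be a function")
  if (!inherits(shift, "shift_config")) stop("shift must be a shift_config")
  structure(list(image_size = image_size,
                 concepts = concepts,
                 n_concepts = length(concepts),
                 class_rule = class_rule,
                 class_rule_id = class_rule_id,
                 split_sizes = split_sizes,
                 presence_prob = presence_prob,
                 base_shape = base_shape,
                 noise_sigma = noise_sigma,
                 shift = shift,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Derive a shifted generator configuration
#'
#' Returns a copy of `config` whose generated images differ from the base
#' distribution in background texture, per-image color statistics, shape
#' scale and pixel noise by the requested deltas. The class rule is untouched,
#' so shifted images carry the same label semantics.
#'
#' @param config A [generator_config()].
#' @param shift A [shift_config()].
#' @return A new `generator_config` with the shift applied.
#' @export
apply_distribution_shift <- function(config, shift) {
  stopifnot(inherits(config, "generator_config"))
  if (!inherits(shift, "shift_config")) stop("shift must be a shift_config")
  config$shift <- shift
  config
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>", x$image_size, "px,", x$n_concepts, "concepts,",
      "splits", paste(x$split_sizes, collapse = "/"),
      "rule", x$class_rule_id, "seed", x$seed, "\n")
  sh <- unlist(x$shift)
  if (any(sh > 0)) cat("  shift:", paste(names(sh), sh, sep = "=", collapse = " "), "\n")
  invisible(x)
}
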