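# Synthetic concept benchmark generator.

test_that("image generation is deterministic and obeys the labeling rule", {
  cfg <- tiny_config(seed = 7L)
  a <- generate_image(cfg, seed = 7)
  b <- generate_image(cfg, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$pixels, generate_image(cfg, seed = 8)$pixels))
  for (s in 1:50) {
    im <- generate_image(cfg, seed = s)
    expect_identical(im$class_label,
                     as.integer(default_class_rule(im$concept_presence)))
    # mask-presence consistency
    expect_identical(lengths(im$concept_mask_idx) > 0L,
                     unname(im$concept_presence == 1L))
    expect_true(all(im$pixels >= 0 & im$pixels <= 1))
  }
})

test_that("default class rule is total over valid vectors and balanced", {
  # exhaustive check of the rule over all 2^8 presence vectors
  all_vec <- as.matrix(expand.grid(rep(list(0:1), 8)))
  lab <- apply(all_vec, 1, default_class_rule)
  c1 <- (all_vec[, 3] & all_vec[, 2]) | all_vec[, 5]
  c0 <- (all_vec[, 6] & all_vec[, 4]) | all_vec[, 8]
  expect_identical(is.na(lab), !xor(c1 == 1, c0 == 1))
  # independent oracle: under p = 1/2 the two branches are symmetric, so
  # valid vectors split classes exactly 50/50; Monte-Carlo counts must land
  # within +/- 5 percentage points
  labs <- vapply(1:1000, function(i) {
    generate_image(tiny_config(), seed = 10000 + i)$class_label
  }, integer(1))
  expect_gt(mean(labs), 0.45)
  expect_lt(mean(labs), 0.55)
})

test_that("class-discriminative evidence is sparse inside the base shape", {
  disc <- c(2, 3, 4, 5, 6, 8)   # concepts referenced by the class rule
  cfg <- tiny_config()
  fr <- vapply(1:200, function(i) {
    im <- generate_image(cfg, seed = 20000 + i)
    blob_area <- pi * (mean(cfg$base_shape$radius_range) * cfg$image_size)^2
    length(unique(unlist(im$concept_mask_idx[disc]))) / blob_area
  }, numeric(1))
  expect_lt(mean(fr), 0.25)
})

test_that("generate_dataset honors split sizes with disjoint ids", {
  b <- tiny_bundle()
  expect_identical(lengths(b[c("train", "val", "test", "concept")]),
                   c(train = 800L, val = 150L, test = 200L, concept = 300L))
  ids <- unlist(lapply(b[c("train", "val", "test", "concept")], function(p)
    vapply(p, function(im) im$sample_id, "")))
  expect_false(anyDuplicated(ids) > 0)
  # configuration echo at another size
  cfg <- generator_config(image_size = 32L,
                          split_sizes = c(train = 10L, val = 5L, test = 5L,
                                          concept = 20L))
  b2 <- generate_dataset(cfg)
  expect_identical(lengths(b2[c("train", "val", "test", "concept")]),
                   c(train = 10L, val = 5L, test = 5L, concept = 20L))
  # reproducibility from the seed
  b3 <- generate_dataset(cfg)
  expect_identical(b2$train[[3]]$pixels, b3$train[[3]]$pixels)
})

test_that("labels are perfectly computable from presence vectors", {
  b <- tiny_bundle()
  for (im in b$test) {
    expect_identical(im$class_label,
                     as.integer(default_class_rule(im$concept_presence)))
  }
})

test_that("distribution shift validates inputs and preserves the rule", {
  cfg <- tiny_config()
  expect_error(shift_config(color_jitter_delta = -0.1), "delta")
  sh <- apply_distribution_shift(cfg, default_shift())
  expect_identical(sh$class_rule, cfg$class_rule)
  for (i in 1:30) {
    im <- generate_image(sh, seed = 5000 + i)
    expect_identical(im$class_label,
                     as.integer(default_class_rule(im$concept_presence)))
  }
  # zero shift reproduces the base distribution bit for bit
  z <- apply_distribution_shift(cfg, shift_config())
  expect_identical(generate_image(z, seed = 3), generate_image(cfg, seed = 3))
})

test_that("noise delta raises per-image pixel sd on paired seeds", {
  cfg <- tiny_config()
  noisy <- apply_distribution_shift(cfg, shift_config(noise_sigma_delta = 0.1))
  wins <- vapply(1:200, function(i) {
    a <- generate_image(cfg, seed = 40000 + i)
    b <- generate_image(noisy, seed = 40000 + i)
    stats::sd(b$pixels) > stats::sd(a$pixels)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("histogram distance to the base distribution grows with each delta", {
  cfg <- tiny_config()
  hist_sig <- function(gcfg, n = 120L) {
    h <- numeric(0)
    for (ch in 1:3) {
      acc <- numeric(20)
      for (i in seq_len(n)) {
        im <- generate_image(gcfg, seed = 60000 + i)
        acc <- acc + graphics::hist(im$pixels[, , ch], breaks = seq(0, 1, 0.05),
                                    plot = FALSE)$counts
      }
      h <- c(h, acc / n)
    }
    h
  }
  base <- hist_sig(cfg)
  dist_to_base <- function(sh) {
    mean(abs(hist_sig(apply_distribution_shift(cfg, sh)) - base))
  }
  d0 <- dist_to_base(shift_config())
  for (field in c("background_texture_delta", "color_jitter_delta",
                  "shape_scale_delta", "noise_sigma_delta")) {
    args_lo <- stats::setNames(list(0.1), field)
    args_hi <- stats::setNames(list(0.3), field)
    d_lo <- dist_to_base(do.call(shift_config, args_lo))
    d_hi <- dist_to_base(do.call(shift_config, args_hi))
    expect_gte(d_lo, d0)
    expect_gte(d_hi, d_lo)
  }
})

test_that("dataset write/read round-trips metadata exactly and pixels to 8 bits", {
  cfg <- generator_config(image_size = 32L,
                          split_sizes = c(train = 6L, val = 2L, test = 2L,
                                          concept = 4L), seed = 5L)
  b <- generate_dataset(cfg)
  d <- withr::local_tempdir()
  write_dataset(b, d)
  meta <- utils::read.csv(file.path(d, "metadata.csv"))
  expect_identical(nrow(meta), 14L)   # one row per image, single header
  expect_identical(names(meta)[1:3], c("sample_id", "split", "class"))
  b2 <- read_dataset(d)
  for (p in c("train", "val", "test", "concept")) {
    expect_identical(vapply(b[[p]], function(im) im$sample_id, ""),
                     vapply(b2[[p]], function(im) im$sample_id, ""))
    expect_identical(vapply(b[[p]], function(im) im$class_label, 0L),
                     vapply(b2[[p]], function(im) im$class_label, 0L))
    for (i in seq_along(b[[p]])) {
      expect_identical(unname(b[[p]][[i]]$concept_presence),
                       unname(b2[[p]][[i]]$concept_presence))
      expect_identical(b[[p]][[i]]$concept_mask_idx,
                       b2[[p]][[i]]$concept_mask_idx)
      expect_lte(max(abs(b[[p]][[i]]$pixels - b2[[p]][[i]]$pixels)), 1 / 255)
    }
  }
  # mask PNG of an absent concept is all zero
  im <- b$train[[1]]
  absent <- which(im$concept_presence == 0L)[1]
  mpng <- png::readPNG(file.path(d, sprintf("%s_c%d.png", im$sample_id,
                                            absent - 1L)))
  expect_true(all(mpng == 0))
  # corrupt store: missing image file is reported with the sample id
  file.remove(file.path(d, paste0(im$sample_id, ".png")))
  expect_error(read_dataset(d), im$sample_id)
})

test_that("downsampling halves resolution and preserves mask semantics", {
  im <- generate_image(tiny_config(), seed = 1)
  dn <- downsample_images(list(im), 2L)[[1]]
  expect_identical(dim(dn$pixels), c(16L, 16L, 3L))
  expect_identical(lengths(dn$concept_mask_idx) > 0L,
                   lengths(im$concept_mask_idx) > 0L)
  expect_equal(mean(dn$pixels), mean(im$pixels), tolerance = 1e-12)
})
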