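# Membership-inference features and attacks.

test_that("prediction-derived scalars match closed forms", {
  mdl <- toy_linear_model(matrix(0, 2, 3), b = c(0, 0))   # uniform predictor
  imgs <- lapply(1:2, function(i) {
    structure(list(pixels = array(0.5, c(1, 1, 3)), class_label = i - 1L,
                   concept_presence = stats::setNames(integer(8), letters[1:8]),
                   concept_mask_idx = rep(list(integer(0)), 8),
                   sample_id = paste0("t", i), image_size = 1L),
              class = "labeled_image")
  })
  f <- extract_features(mdl, imgs)
  # uniform (0.5, 0.5): entropy ln 2, confidence 0.5, variance 0
  expect_equal(f$entropy, rep(log(2), 2), tolerance = 1e-10)
  expect_equal(f$max_confidence, rep(0.5, 2), tolerance = 1e-10)
  expect_equal(f$variance, rep(0, 2), tolerance = 1e-12)
  expect_equal(f$loss, rep(-log(0.5), 2), tolerance = 1e-10)
  # a (1, 0)-like prediction: entropy 0, variance 0.25
  mdl2 <- toy_linear_model(matrix(0, 2, 3), b = c(40, 0))
  f2 <- extract_features(mdl2, imgs[1])
  expect_equal(f2$entropy, 0, tolerance = 1e-8)
  expect_equal(f2$variance, 0.25, tolerance = 1e-8)
  # correct-class probability 0.9 -> loss -ln 0.9
  p <- 0.9
  mdl3 <- toy_linear_model(matrix(0, 2, 3), b = c(log(p / (1 - p)), 0))
  expect_equal(extract_features(mdl3, imgs[1])$loss, -log(0.9),
               tolerance = 1e-9)
})

test_that("metric AUC equals brute-force pair counting, including ties", {
  brute <- function(s, m) {
    ms <- s[m]; ns <- s[!m]
    tot <- 0
    for (a in ms) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
    100 * tot / (length(ms) * length(ns))
  }
  # worked example: members {0.9, 0.4}, non-members {0.5, 0.1} -> 3/4 pairs
  expect_equal(metric_attack_auc(c(0.9, 0.4, 0.5, 0.1),
                                 c(TRUE, TRUE, FALSE, FALSE)), 75)
  expect_equal(metric_attack_auc(c(0.9, 0.8, 0.1, 0.2),
                                 c(TRUE, TRUE, FALSE, FALSE)), 100)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:200, 1)
    memb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(memb) || all(memb)) memb[1:2] <- c(TRUE, FALSE)
    # draw from a small discrete set so ties occur often
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    expect_equal(metric_attack_auc(sc, memb), brute(sc, memb),
                 tolerance = 1e-10)
  }
  # random scores sit at chance within Monte-Carlo tolerance
  set.seed(0)
  sc <- stats::runif(2000)
  memb <- rep(c(TRUE, FALSE), 1000)
  expect_lt(abs(metric_attack_auc(sc, memb) - 50), 3)
  expect_error(metric_attack_auc(sc, rep(TRUE, 2000)), "both")
})

.fake_features <- function(n, f = 4L, seed = 1L, groups = c("TP")) {
  set.seed(seed)
  out <- list(ids = sprintf("s%04d", 1:n),
              prediction = matrix(stats::runif(n * 2), n, 2),
              loss = stats::runif(n), max_confidence = stats::runif(n),
              entropy = stats::runif(n), variance = stats::runif(n),
              membership = rep(c(TRUE, FALSE), n / 2))
  if ("CP" %in% groups) out$concept <- matrix(stats::runif(n * f), n, f)
  structure(out, class = "sample_features")
}

test_that("attack vectors are standardized per group on the training portion", {
  f <- .fake_features(200, groups = c("TP", "CP"))
  spec <- attack_vector_spec(c("TP", "CP"))
  ds <- assemble_attack_vector(f, spec, split = c(0.67, 0.33), seed = 1L)
  tr <- ds$portion == "train"
  expect_lt(max(abs(colMeans(ds$x[tr, ]))), 1e-6)
  expect_equal(unname(apply(ds$x[tr, ], 2, stats::sd)), rep(1, ncol(ds$x)),
               tolerance = 1e-6)
  expect_identical(ncol(ds$x), 2L + 4L)
  expect_identical(ds$spec$groups, c("TP", "CP"))
  # {TP} on a 2-class problem: length-2 vectors
  ds2 <- assemble_attack_vector(.fake_features(100), attack_vector_spec("TP"))
  expect_identical(ncol(ds2$x), 2L)
  # per-group standardization differs from joint standardization when group
  # variances differ (constructed counterexample: variances 1 vs 100)
  g1 <- matrix(stats::rnorm(400), 200, 2)
  g2 <- matrix(stats::rnorm(400, sd = 10), 200, 2)
  fj <- .fake_features(200)
  fj$prediction <- g1
  fj$concept <- g2
  dsp <- assemble_attack_vector(fj, attack_vector_spec(c("TP", "CP")),
                                seed = 2L)
  joint <- scale(cbind(g1, g2))
  # the per-group result equals per-column scaling here (columns are the
  # unit), but differs from scaling the concatenation by the pooled sd
  pooled <- cbind(g1, g2) / stats::sd(cbind(g1, g2))
  expect_false(isTRUE(all.equal(unname(dsp$x), unname(pooled),
                                tolerance = 1e-3)))
  # zero-variance features map to 0
  fz <- .fake_features(100)
  fz$prediction[, 2] <- 7
  dz <- assemble_attack_vector(fz, attack_vector_spec("TP"))
  expect_true(all(dz$x[, 2] == 0))
  # non-finite features are rejected with group and sample named
  fn <- .fake_features(100)
  fn$prediction[3, 1] <- NaN
  expect_error(assemble_attack_vector(fn, attack_vector_spec("TP")),
               "TP.*s0003")
})

test_that("membership splits are exactly balanced in every portion", {
  f <- .fake_features(300, seed = 5L)
  for (spl in list(c(0.67, 0.33), c(0.45, 0.22, 0.33))) {
    ds <- assemble_attack_vector(f, attack_vector_spec("TP"), split = spl,
                                 seed = 3L)
    tab <- table(ds$portion, ds$membership)
    expect_true(all(tab[, 1] == tab[, 2]))
  }
  fu <- .fake_features(100)
  fu$membership <- rep(c(TRUE, FALSE), c(60, 40))
  expect_error(assemble_attack_vector(fu, attack_vector_spec("TP")),
               "balanced")
})

test_that("svm attack separates separable data and stays at chance on noise", {
  n <- 400
  x <- matrix(stats::rnorm(n * 4, sd = 0.1), n, 4)
  memb <- rep(c(TRUE, FALSE), n / 2)
  x[memb, 1] <- x[memb, 1] + 1
  x[!memb, 1] <- x[!memb, 1] - 1
  f <- .fake_features(n, seed = 7L)
  f$prediction <- x
  ds <- assemble_attack_vector(f, attack_vector_spec("TP"), seed = 1L)
  expect_equal(svm_attack(ds, seed = 1L)$value, 100, tolerance = 1)
  # permutation null at n = 1000
  f0 <- .fake_features(1000, seed = 8L)
  ds0 <- assemble_attack_vector(f0, attack_vector_spec("TP"), seed = 2L)
  v <- svm_attack(ds0, seed = 1L)$value
  expect_lt(abs(v - 50), 5)
  # duplicating every sample leaves the (informative) attack unchanged
  fdup <- f
  for (nm in c("prediction", "loss", "max_confidence", "entropy", "variance")) {
    fdup[[nm]] <- if (is.matrix(f[[nm]])) rbind(f[[nm]], f[[nm]]) else
      c(f[[nm]], f[[nm]])
  }
  fdup$ids <- c(f$ids, paste0(f$ids, "b"))
  fdup$membership <- c(f$membership, f$membership)
  dsd <- assemble_attack_vector(fdup, attack_vector_spec("TP"), seed = 2L)
  expect_lt(abs(svm_attack(dsd, seed = 1L)$value -
                  svm_attack(ds, seed = 1L)$value), 1 + 1e-9)
})

test_that("fc attack learns separable membership and stays at chance on permuted labels", {
  n <- 600
  x <- matrix(stats::rnorm(n * 6, sd = 0.05), n, 6)
  memb <- rep(c(TRUE, FALSE), n / 2)
  x[memb, 2] <- x[memb, 2] + 1
  f <- .fake_features(n, seed = 9L)
  f$prediction <- x[, 1:2]
  f$concept <- x[, 3:6]
  ds <- assemble_attack_vector(f, attack_vector_spec(c("TP", "CP")),
                               split = c(0.45, 0.22, 0.33), seed = 1L)
  r <- nn_attack_fc(ds, seed = 1L)
  expect_gte(r$value, 99)
  # early stopping: training ends within patience epochs of the best epoch
  expect_lte(nrow(r$log), r$best_epoch + 10)
  # null calibration at n = 1000
  f0 <- .fake_features(1000, seed = 10L)
  ds0 <- assemble_attack_vector(f0, attack_vector_spec("TP"),
                                split = c(0.45, 0.22, 0.33), seed = 1L)
  expect_lt(abs(nn_attack_fc(ds0, seed = 1L)$value - 50), 5)
})

test_that("cnn attack pads vectors to grids and behaves at the null", {
  g <- pad_to_grid(1:10, channels = 1L)
  expect_identical(dim(g), c(4L, 4L, 1L))
  expect_equal(as.numeric(t(g[, , 1])), c(1:10, rep(0, 6)))
  n <- 600
  x <- matrix(stats::rnorm(n * 10, sd = 0.05), n, 10)
  memb <- rep(c(TRUE, FALSE), n / 2)
  x[memb, ] <- x[memb, ] + 1
  f <- .fake_features(n, seed = 11L)
  f$prediction <- x
  ds <- assemble_attack_vector(f, attack_vector_spec("TP"),
                               split = c(0.45, 0.22, 0.33), seed = 1L)
  expect_gte(nn_attack_cnn(ds, seed = 1L)$value, 95)
  # all-zero vectors carry no signal
  fz <- .fake_features(1000, seed = 12L)
  fz$prediction <- matrix(0, 1000, 8)
  fz$prediction[, 1] <- stats::rnorm(1000) * 1e-9
  dz <- assemble_attack_vector(fz, attack_vector_spec("TP"),
                               split = c(0.45, 0.22, 0.33), seed = 1L)
  expect_lt(abs(nn_attack_cnn(dz, seed = 1L)$value - 50), 5)
})

test_that("feature-spec strings parse into ordered groups", {
  sp <- parse_feature_spec("TP+CP+pCLM")
  expect_identical(sp$groups, c("TP", "CP", "pCLM"))
  expect_error(parse_feature_spec("TP+XX"), "unknown")
  expect_error(attack_vector_spec(character(0)), "at least one")
})
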