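# Attribution maps, CAVs, TCAV scores and concept localization maps.

test_that("saliency of a linear model equals the absolute weights, channel-maxed", {
  # toy model on 2x2 images: logit = w . features (channel-fastest order)
  set.seed(4)
  W <- matrix(stats::rnorm(2 * 12), 2, 12)
  m <- toy_linear_model(W)
  img <- array(stats::runif(2 * 2 * 3), c(2, 2, 3))
  sal <- saliency(m, img, 1L)
  # gradient w.r.t. the raw input includes the 1/0.25 normalization factor
  wf <- array(W[1, ], c(3, 2, 2)) / 0.25
  expected <- apply(abs(aperm(wf, c(2, 3, 1))), c(1, 2), max)
  expect_equal(sal$values, expected, tolerance = 1e-10)
  # scaling the logits scales the map linearly
  m3 <- toy_linear_model(3 * W)
  expect_equal(saliency(m3, img, 1L)$values, 3 * sal$values, tolerance = 1e-10)
  # constant model: zero map
  m0 <- toy_linear_model(matrix(0, 2, 12), b = c(1, -1))
  expect_true(all(saliency(m0, img, 1L)$values == 0))
})

test_that("occlusion matches the definitional toy case and a brute-force oracle", {
  # 4x4 image, score = sum of pixels, window 2 stride 2, fill 0, all ones:
  # each occlusion removes its own 4 ones from one channel-summed score
  img1 <- array(1, c(4, 4, 3))
  sum_score <- function(xb) apply(xb, 4, sum)
  m <- occlusion(sum_score, img1, window = 2L, stride = 2L, fill = 0)
  expect_equal(m$values, matrix(12, 4, 4), tolerance = 1e-10) # 4 px x 3 ch
  # constant score: all-zero map
  const_score <- function(xb) rep(2, dim(xb)[4])
  expect_true(all(occlusion(const_score, img1, window = 2L,
                            stride = 2L)$values == 0))
  # brute-force oracle on a real victim with overlapping windows
  mdl <- tiny_baseline()
  img <- tiny_bundle()$test[[1]]$pixels
  got <- occlusion(mdl, img, 1L, window = 12L, stride = 5L)$values
  oracle <- local({
    S <- dim(img)[1]
    starts <- function(side) {
      s <- seq(1L, side - 12L + 1L, by = 5L)
      if (s[length(s)] + 11L < side) s <- c(s, side - 11L)
      s
    }
    fill <- mean(img)
    clean <- predict_proba(mdl, img)[1, 1]
    v <- matrix(0, S, S); cnt <- matrix(0, S, S)
    for (r in starts(S)) for (cc in starts(S)) {
      x2 <- img
      x2[r:(r + 11L), cc:(cc + 11L), ] <- fill
      d <- clean - predict_proba(mdl, x2)[1, 1]
      v[r:(r + 11L), cc:(cc + 11L)] <- v[r:(r + 11L), cc:(cc + 11L)] + d
      cnt[r:(r + 11L), cc:(cc + 11L)] <- cnt[r:(r + 11L), cc:(cc + 11L)] + 1
    }
    v / pmax(cnt, 1)
  })
  expect_lt(max(abs(got - oracle)), 1e-6)
  expect_error(occlusion(mdl, img, 1L, stride = 0L), "stride")
  expect_error(occlusion(mdl, img, 9L), "out of range")
})

test_that("train_cav recovers separable directions and flips with labels", {
  pos <- matrix(rep(c(1, 0), each = 40), 40, 2)
  neg <- matrix(rep(c(-1, 0), each = 40), 40, 2)
  cv <- train_cav(pos + stats::rnorm(80, sd = 0.01),
                  neg + stats::rnorm(80, sd = 0.01), seed = 1L)
  expect_equal(sqrt(sum(cv$direction^2)), 1, tolerance = 1e-6)
  expect_gt(cv$direction[1], 0.99)
  expect_equal(cv$test_accuracy, 100)
  cv2 <- train_cav(neg + stats::rnorm(80, sd = 0.01),
                   pos + stats::rnorm(80, sd = 0.01), seed = 1L)
  expect_lt(sum(cv$direction * cv2$direction), -0.99)
  expect_error(train_cav(pos, matrix(nrow = 0, ncol = 2)), "non|required")
})

test_that("held-out CAV accuracy approaches the Bayes rate on Gaussian classes", {
  # N(+mu, I) vs N(-mu, I) in 10-d: Bayes accuracy = Phi(|2 mu| / 2)
  set.seed(8)
  mu <- rep(0.5, 10) / sqrt(10)           # ||2 mu|| = 1 -> Phi(0.5) = 69.1%
  pos <- matrix(stats::rnorm(200 * 10), 200, 10) +
    matrix(mu, 200, 10, byrow = TRUE)
  neg <- matrix(stats::rnorm(200 * 10), 200, 10) -
    matrix(mu, 200, 10, byrow = TRUE)
  bayes <- 100 * stats::pnorm(1 / 2)
  accs <- vapply(1:5, function(s) train_cav(pos, neg, seed = s)$test_accuracy,
                 numeric(1))
  expect_lt(abs(mean(accs) - bayes), 5)
})

test_that("cav_ensemble statistics match brute-force recomputation", {
  mdl <- tiny_baseline()
  ens <- tiny_ensembles(mdl)[[3]]     # the star concept
  expect_equal(sqrt(sum(ens$mean_direction^2)), 1, tolerance = 1e-6)
  expect_true(isSymmetric(ens$cosine_matrix, tol = 1e-10))
  expect_equal(unname(diag(ens$cosine_matrix)), rep(1, ens$n), tolerance = 1e-6)
  # off-diagonal mean vs independent double loop over member directions
  dirs <- lapply(ens$cavs, function(cv) cv$direction)
  s <- 0; cnt <- 0
  for (i in seq_along(dirs)) for (j in seq_along(dirs)) {
    if (i < j) { s <- s + sum(dirs[[i]] * dirs[[j]]); cnt <- cnt + 1 }
  }
  expect_equal(mean(ens$cosine_matrix[upper.tri(ens$cosine_matrix)]), s / cnt,
               tolerance = 1e-10)
  # accuracy stats vs direct recomputation
  accs <- vapply(ens$cavs, function(cv) cv$test_accuracy, numeric(1))
  expect_equal(ens$accuracy_mean, mean(accs))
  expect_equal(ens$accuracy_std, stats::sd(accs))
  # n = 1 degenerates to the single member
  arr <- as_image_array(tiny_bundle()$concept)
  act <- explainleak:::.batched_activations(mdl, arr$x, "gap")
  e1 <- cav_ensemble(mdl, "gap", tiny_bundle()$concept, 3L, n = 1L,
                     activations = act)
  expect_equal(e1$mean_direction, e1$cavs[[1]]$direction, tolerance = 1e-10)
  # deterministic classes with no undersampling variability: cosines ~ 1
  det_act <- rbind(matrix(rep(c(5, 0, 0, 0), each = 30), 30),
                   matrix(rep(c(-5, 0, 0, 0), each = 30), 30))
  det_imgs <- lapply(seq_len(60), function(i) {
    im <- tiny_bundle()$concept[[i]]
    im$concept_presence[] <- c(rep(1L, 30), rep(0L, 30))[i]
    im
  })
  # equal class sizes -> undersampling keeps everything; members coincide
  e_det <- cav_ensemble(mdl, "gap", det_imgs, 1L, n = 5L,
                        activations = det_act)
  expect_true(all(abs(e_det$cosine_matrix - 1) < 1e-6))
})

test_that("concept scores sit at 0.5 on the hyperplane and saturate far away", {
  mdl <- tiny_baseline()
  ens <- tiny_ensembles(mdl)[[3]]
  v <- ens$mean_direction
  ic <- ens$calibration[["intercept"]]; sl <- ens$calibration[["slope"]]
  # feature vectors constructed exactly on / far from the decision boundary
  a_mid <- v * (-ic / sl)                    # projection = -intercept/slope
  a_far <- v * ((sign(sl) * 50 - ic) / sl)
  score <- function(a) {
    z <- ic + sl * sum(a * v); 1 / (1 + exp(-z))
  }
  expect_equal(score(a_mid), 0.5, tolerance = 1e-9)
  expect_gt(score(a_far), 0.99)
  # package path agrees with the closed form on real images
  x <- as_image_array(tiny_bundle()$test[1:8])$x
  sc <- concept_predictions(mdl, x, tiny_ensembles(mdl))
  expect_identical(dim(sc), c(8L, 8L))
  expect_true(all(sc >= 0 & sc <= 1))
  acts <- activations_at(mdl, x, "gap")
  byhand <- 1 / (1 + exp(-(ic + sl * as.numeric(acts %*% v))))
  expect_equal(sc[, 3], byhand, tolerance = 1e-10)
  # mismatched layers across ensembles are rejected
  bad <- tiny_ensembles(mdl)
  bad[[2]]$layer <- "block1"
  expect_error(concept_predictions(mdl, x, bad), "layer")
})

test_that("thresholded concept scores recover ground-truth presence", {
  mdl <- medium_baseline()
  ens <- medium_ensembles()
  te <- as_image_array(medium_bundle()$test)
  sc <- concept_predictions(mdl, te$x, ens)
  acc <- vapply(1:8, function(k) {
    100 * mean((sc[, k] > 0.5) == (te$presence[, k] == 1L))
  }, numeric(1))
  held <- vapply(ens, function(e) e$accuracy_mean, numeric(1))
  expect_true(all(acc >= held - 5))
})

test_that("tcav_score counts strictly positive directional derivatives", {
  # model: flatten ("gap" probe) -> relu -> fc with W = (1,1,1); the
  # gradient at the probe is W masked by each sample's ReLU pattern
  W <- matrix(c(1, 1, 1), 1, 3)
  m <- toy_linear_model(rbind(W, 0), probe = "relu_above")
  masks <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  x <- images_from_features(2 * masks - 1)   # positive where mask = 1
  v <- c(0.2, -0.1, 0.5)
  d <- directional_derivatives(m, "gap", v, x, 1L)
  expect_equal(d, c(0.2, -0.1, 0.5), tolerance = 1e-10)
  expect_equal(tcav_score(m, "gap", v, x, 1L), 2 / 3)
  # all-positive and all-negative edge cases stay within [0, 1]
  expect_equal(tcav_score(m, "gap", c(1, 1, 1), x, 1L), 1)
  expect_equal(tcav_score(m, "gap", -c(1, 1, 1), x, 1L), 0)
  # orthogonal direction: derivative identically zero is NOT > 0
  m_lin <- toy_linear_model(rbind(c(1, 0, 0), 0))   # probe = raw features
  xr <- images_from_features(matrix(stats::rnorm(15), 5, 3))
  expect_equal(tcav_score(m_lin, "gap", c(0, 1, 0), xr, 1L), 0)
  # self-alignment: CAV equal to the constant gradient direction
  expect_equal(tcav_score(m_lin, "gap", c(1, 0, 0), xr, 1L), 1)
  # complementary scores sum to at most 1
  mdl <- tiny_baseline()
  ens <- tiny_ensembles(mdl)[[5]]
  cls1 <- as_image_array(Filter(function(im) im$class_label == 1L,
                                tiny_bundle()$test[1:60]))$x
  s_pos <- tcav_score(mdl, "gap", ens$mean_direction, cls1, 2L)
  s_neg <- tcav_score(mdl, "gap", -ens$mean_direction, cls1, 2L)
  expect_true(s_pos >= 0 && s_pos <= 1)
  expect_lte(s_pos + s_neg, 1 + 1e-10)
  expect_error(tcav_score(mdl, "gap", ens$mean_direction,
                          cls1[, , , 0, drop = FALSE], 2L), "empty")
})

test_that("g-CLM matches finite differences and the identity-network case", {
  # identity probe: activation = flattened input, CAV = e1 -> only feature 1
  # (channel 1 of pixel (1,1)) gets relevance
  m_lin <- toy_linear_model(matrix(c(1, 1, 1, 0, 0, 0), 2, 3, byrow = TRUE))
  ens_e1 <- structure(list(mean_direction = c(1, 0, 0), layer = "gap",
                           concept_id = 1L,
                           calibration = c(intercept = 0, slope = 1)),
                      class = "cav_ensemble")
  img <- array(stats::runif(3), c(1, 1, 3))
  gm <- g_clm(m_lin, img, ens_e1)
  expect_equal(gm$values[1, 1], 1 / 0.25, tolerance = 1e-10)
  # real model: finite-difference check of the concept score d(a.v)/dx
  mdl <- tiny_baseline()
  ens <- tiny_ensembles(mdl)[[2]]
  img2 <- tiny_bundle()$test[[2]]$pixels
  x <- explainleak:::.as_batch(img2)
  a0 <- sum(activations_at(mdl, x, "gap")[1, ] * ens$mean_direction)
  g <- explainleak:::.input_gradient_from_layer(
    mdl, x, "gap", matrix(ens$mean_direction, ncol = 1))
  set.seed(3)
  for (i in 1:10) {
    rc <- sample(32, 2); ch <- sample(3, 1)
    x2 <- x; x2[rc[1], rc[2], ch, 1] <- x2[rc[1], rc[2], ch, 1] + 1e-5
    a1 <- sum(activations_at(mdl, x2, "gap")[1, ] * ens$mean_direction)
    fd <- (a1 - a0) / 1e-5
    an <- g[rc[1], rc[2], ch, 1]
    expect_equal(an, fd, tolerance = max(1e-3, 1e-3 * abs(fd)))
  }
})

test_that("p-CLM is zero under identity blur and matches brute force", {
  mdl <- tiny_baseline()
  ens <- tiny_ensembles(mdl)[[3]]
  img <- tiny_bundle()$test[[3]]$pixels
  z <- p_clm(mdl, img, ens, window = 12L, stride = 6L, blur_sigma = 0)
  expect_true(all(z$values == 0))
  got <- p_clm(mdl, img, ens, window = 12L, stride = 6L)$values
  # independent per-window recomputation
  oracle <- local({
    S <- dim(img)[1]; win <- 12L
    blurred <- explainleak:::.gaussian_blur(img, win / 4)
    ctr <- (win + 1) / 2
    wgt <- exp(-(outer((seq_len(win) - ctr)^2, (seq_len(win) - ctr)^2, "+")) /
                 (2 * (win / 4)^2))
    starts <- function(side) {
      s <- seq(1L, side - win + 1L, by = 6L)
      if (s[length(s)] + win - 1L < side) s <- c(s, side - win + 1L)
      s
    }
    cscore <- function(im) concept_predictions(mdl, explainleak:::.as_batch(im),
                                               list(ens))[1, 1]
    clean <- cscore(img)
    v <- matrix(0, S, S); cnt <- matrix(0, S, S)
    for (r in starts(S)) for (cc in starts(S)) {
      ri <- r:(r + win - 1L); ci <- cc:(cc + win - 1L)
      x2 <- img
      for (ch in 1:3) {
        x2[ri, ci, ch] <- wgt * blurred[ri, ci, ch] + (1 - wgt) * x2[ri, ci, ch]
      }
      d <- clean - cscore(x2)
      v[ri, ci] <- v[ri, ci] + d
      cnt[ri, ci] <- cnt[ri, ci] + 1
    }
    v / pmax(cnt, 1)
  })
  expect_lt(max(abs(got - oracle)), 1e-6)
})

test_that("p-CLM mass concentrates inside ground-truth concept masks", {
  mdl <- medium_baseline()
  b <- medium_bundle()
  wins <- 0L
  for (k in 1:8) {
    ratios <- c()
    for (im in b$test[1:80]) {
      if (im$concept_presence[k] != 1L) next
      mp <- p_clm(mdl, im$pixels, medium_ensembles()[[k]])
      mask <- concept_mask(im, k)
      inside <- mean(mp$values[mask == 1])
      outside <- mean(mp$values[mask == 0])
      ratios <- c(ratios, inside - outside)
      if (length(ratios) >= 10) break
    }
    if (mean(ratios) > 0) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("occlusion maps translate with the evidence (toy sum-score model)", {
  # score = sum over a bright square; moving the square by one stride moves
  # the argmax window of the map accordingly
  S <- 24L
  mk <- function(at) {
    img <- array(0, c(S, S, 3))
    img[at:(at + 3L), at:(at + 3L), ] <- 1
    img
  }
  sum_score <- function(xb) apply(xb, 4, sum)
  m1 <- occlusion(sum_score, mk(5L), window = 6L, stride = 3L, fill = 0)$values
  m2 <- occlusion(sum_score, mk(8L), window = 6L, stride = 3L, fill = 0)$values
  expect_equal(which.max(apply(m2, 1, max)) - which.max(apply(m1, 1, max)), 3L)
})
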