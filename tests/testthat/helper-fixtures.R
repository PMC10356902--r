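# Shared fixtures, memoized per test run. Everything is generated in code at
# fixed seeds; sizes are chosen so the whole suite stays desk-scale.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(name, fn) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, fn(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# tiny bundle: fast unit-test substrate (32 px, small splits)
tiny_config <- function(seed = 0L) {
  generator_config(image_size = 32L,
                   split_sizes = c(train = 800L, val = 150L, test = 200L,
                                   concept = 300L),
                   seed = seed)
}

tiny_bundle <- function() .memo("tiny_bundle", function() {
  generate_dataset(tiny_config())
})

tiny_shifted_pool <- function(n = 200L) .memo("tiny_shifted", function() {
  cfg <- apply_distribution_shift(tiny_config(), default_shift())
  lapply(seq_len(n), function(i) {
    generate_image(cfg, seed = 900000 + i, sample_id = sprintf("shift_%04d", i))
  })
})

tiny_baseline <- function() .memo("tiny_baseline", function() {
  m <- build_model(arch_config("small_cnn", width = 8L), seed = 1L)
  tc <- train_config("baseline", lr_grid = 0.1, max_epochs = 40L,
                     early_stop_patience = 12, plateau_patience = 6, seed = 0L)
  train_baseline(m, tiny_bundle(), tc)
})

tiny_overfit <- function() .memo("tiny_overfit", function() {
  m <- build_model(arch_config("small_cnn", width = 8L), seed = 1L)
  tc <- train_config("overfit", lr_grid = 0.05, max_epochs = 40L,
                     batch_size = 64L, seed = 0L)
  train_overfit(m, tiny_bundle(), tc)
})

tiny_dp <- function() .memo("tiny_dp", function() {
  m <- build_model(arch_config("small_cnn", width = 8L), seed = 1L)
  tc <- train_config("dp", lr_grid = 0.05, max_epochs = 3L,
                     batch_size = 64L, seed = 0L)
  train_dp(m, tiny_bundle(), tc, dp_config(target_epsilon = 5, delta = 1e-4))
})

tiny_ensembles <- function(model, n = 10L) {
  key <- paste0("ens_", substr(digest_of_model(model), 1, 8))
  .memo(key, function() {
    arr <- as_image_array(tiny_bundle()$concept)
    act <- explainleak:::.batched_activations(model, arr$x, "gap")
    lapply(1:8, function(k) {
      cav_ensemble(model, "gap", tiny_bundle()$concept, k, n = n,
                   activations = act)
    })
  })
}

digest_of_model <- function(model) {
  f <- tempfile(); on.exit(unlink(f))
  saveRDS(explainleak:::.par_tree(model$layers), f, compress = FALSE)
  unname(tools::md5sum(f))
}

# medium bundle: the acceptance-criteria substrate (64 px, scaled-down
# splits; the victim reaches weighted F1 in the mid/high 90s)
medium_bundle <- function() .memo("medium_bundle", function() {
  cfg <- generator_config(image_size = 64L,
                          split_sizes = c(train = 2000L, val = 400L,
                                          test = 500L, concept = 1200L),
                          seed = 0L)
  generate_dataset(cfg)
})

medium_baseline <- function() .memo("medium_baseline", function() {
  m <- build_model(arch_config("small_cnn", width = 16L), seed = 1L)
  tc <- train_config("baseline", lr_grid = 0.1, max_epochs = 22L,
                     early_stop_patience = 8, plateau_patience = 4, seed = 0L)
  train_baseline(m, medium_bundle(), tc)
})

# hand-built miniature "victim": flatten -> relu -> linear, with
# controllable weights; used for analytic explanation tests. The layer
# named "gap" is the probe layer for CAV/TCAV code paths: either the raw
# flattened input (probe = "flatten") or the post-ReLU features
# (probe = "relu"). Input features are in channel-fastest order (c, h, w)
# and pass through the model's input normalization (x - 0.5) / 0.25.
toy_linear_model <- function(W, b = NULL, probe = c("input", "relu_above")) {
  probe <- match.arg(probe)
  nf <- ncol(W)
  if (probe == "input") {
    # purely linear: logit = W . flattened internal features
    layers <- list(explainleak:::nn_flatten("gap"),
                   explainleak:::nn_linear(nf, nrow(W), "fc", seed = 1L))
    names(layers) <- c("gap", "fc")
  } else {
    # a ReLU above the probed layer makes the gradient at "gap" depend on
    # each sample's activation pattern
    layers <- list(explainleak:::nn_flatten("gap"),
                   explainleak:::nn_relu("relu"),
                   explainleak:::nn_linear(nf, nrow(W), "fc", seed = 1L))
    names(layers) <- c("gap", "relu", "fc")
  }
  layers$fc$params$W <- W
  layers$fc$params$b <- if (is.null(b)) numeric(nrow(W)) else b
  structure(list(layers = layers,
                 arch = arch_config("small_cnn", width = 1L,
                                    num_classes = nrow(W))),
            class = "victim_model")
}

medium_ensembles <- function() .memo("medium_ensembles", function() {
  mdl <- medium_baseline()
  arr <- as_image_array(medium_bundle()$concept)
  act <- explainleak:::.batched_activations(mdl, arr$x, "gap")
  lapply(1:8, function(k) {
    cav_ensemble(mdl, "gap", medium_bundle()$concept, k, n = 30L,
                 activations = act)
  })
})

# images whose flattened internal features equal `feat` rows (undoes the
# input normalization); feat is N x (3*H*W) in channel-fastest order
images_from_features <- function(feat, H = 1L, Wd = 1L) {
  n <- nrow(feat)
  x <- array(0, c(H, Wd, 3L, n))
  for (i in seq_len(n)) {
    xi <- array(feat[i, ], c(3L, H, Wd))       # internal (C, H, W)
    x[, , , i] <- aperm(xi * 0.25 + 0.5, c(2, 3, 1))
  }
  x
}
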