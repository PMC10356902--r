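# Experiment driver: config parsing, seed fan-out, stage caching, logging.

#' Default experiment configuration
#'
#' @param image_size Generator resolution.
#' @param split_sizes Generator portion sizes.
#' @param victims List of lists with `arch` (family), `width`, `regime`.
#' @param epochs Named epoch budgets per regime.
#' @param lr Learning rate (single-value grid).
#' @param scenarios Scenario names to run.
#' @param feature_groups Feature groups for metric attacks.
#' @param n_per_side Scenario side size.
#' @param target_epsilon,delta DP budget.
#' @param seed Global experiment seed (fans out to per-stage seeds by fixed
#'   offsets).
#' @param out_dir Artifact directory.
#' @return An `experiment_config` (plain list, fully serializable).
#' @export
experiment_config <- function(image_size = 64L,
                              split_sizes = c(train = 4800L, val = 1200L,
                                              test = 1500L, concept = 6000L),
                              victims = list(
                                list(arch = "small_cnn", width = 12L,
                                     regime = "baseline")),
                              epochs = c(baseline = 20L, overfit = 50L, dp = 4L),
                              lr = 0.1,
                              scenarios = c("optimal", "suboptimal"),
                              feature_groups = "prediction",
                              n_per_side = 500L,
                              target_epsilon = 5, delta = 1e-5,
                              seed = 0L, out_dir = "experiment_out") {
  cfg <- list(image_size = as.integer(image_size),
              split_sizes = split_sizes, victims = victims,
              epochs = epochs, lr = lr, scenarios = scenarios,
              feature_groups = feature_groups,
              n_per_side = as.integer(n_per_side),
              target_epsilon = target_epsilon, delta = delta,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "experiment_config"
  cfg
}

.known_config_keys <- function() {
  names(experiment_config())
}

#' Read an experiment configuration from a YAML file
#'
#' Unknown keys are rejected by name.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .known_config_keys())
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$split_sizes)) raw$split_sizes <- unlist(raw$split_sizes)
  if (!is.null(raw$epochs)) raw$epochs <- unlist(raw$epochs)
  do.call(experiment_config, raw)
}

.config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, compress = FALSE)
  unname(tools::md5sum(f))
}

.stage_log <- function(dir, stage, msg, t0 = NULL) {
  line <- sprintf("[%s] %s", stage, msg)
  cat(line, "\n")
  ev <- list(stage = stage, message = msg,
             elapsed_s = if (is.null(t0)) NA else round((proc.time() - t0)[3], 2))
  cat(jsonlite::toJSON(ev, auto_unbox = TRUE), "\n",
      file = file.path(dir, "events.jsonl"), append = TRUE, sep = "")
  cat(line, "\n", file = file.path(dir, "run.log"), append = TRUE, sep = "")
}

# cache a stage result keyed on the hash of its inputs
.cached_stage <- function(dir, stage, key_obj, fn, log = TRUE) {
  key <- .config_hash(key_obj)
  path <- file.path(dir, "cache", paste0(stage, "-", key, ".rds"))
  if (file.exists(path)) {
    if (log) .stage_log(dir, stage, paste("cache hit", key))
    return(readRDS(path))
  }
  t0 <- proc.time()
  res <- fn()
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(res, path)
  if (log) .stage_log(dir, stage, paste("computed", key), t0)
  res
}

#' Run a full experiment
#'
#' generate -> train -> explain -> attack -> report, with per-stage caching
#' keyed on the hash of each stage's configuration (re-running with the same
#' config reuses cached victims and datasets). All stage seeds are derived
#' from the global seed by fixed offsets. The resolved configuration and a
#' manifest of stage hashes are written next to the outputs.
#'
#' @param config An `experiment_config`, or the path of a YAML file.
#' @param dry_run Print the resolved grid and write nothing.
#' @return The results data.frame (invisibly); artifacts under
#'   `config$out_dir`.
#' @export
run_experiment <- function(config, dry_run = FALSE) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  grid <- expand.grid(victim = vapply(config$victims, function(v)
    paste(v$arch, v$regime, sep = "-"), ""),
    scenario = config$scenarios, stringsAsFactors = FALSE)
  if (dry_run) {
    cat("resolved grid (", nrow(grid), "cells ):\n")
    print(grid)
    return(invisible(NULL))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))
  manifest <- list()

  gen_cfg <- generator_config(image_size = config$image_size,
                              split_sizes = config$split_sizes,
                              seed = .fan_seed(config$seed, 1L))
  bundle <- .cached_stage(config$out_dir, "generate", gen_cfg,
                          function() generate_dataset(gen_cfg))
  manifest$generate <- .config_hash(gen_cfg)

  shifted_cfg <- apply_distribution_shift(gen_cfg, default_shift())
  shifted_cfg$seed <- as.integer(.fan_seed(config$seed, 6L))
  need_shift <- "suboptimal" %in% config$scenarios
  shifted_pool <- if (need_shift) {
    .cached_stage(config$out_dir, "generate-shifted",
                  list(shifted_cfg, config$n_per_side), function() {
      lapply(seq_len(config$n_per_side), function(i) {
        generate_image(shifted_cfg, seed = .fan_seed(shifted_cfg$seed, 1L, i),
                       sample_id = sprintf("shifted_%06d", i))
      })
    })
  } else NULL

  victims <- list()
  for (v in config$victims) {
    vn <- paste(v$arch, v$regime, sep = "-")
    key <- list(v, gen_cfg, config$epochs[[v$regime]], config$lr, config$seed)
    victims[[vn]] <- .cached_stage(config$out_dir, paste0("train-", vn), key,
      function() {
        arch <- arch_config(v$arch, width = v$width)
        model <- build_model(arch, seed = .fan_seed(config$seed, 3L))
        tc <- train_config(v$regime, lr_grid = config$lr,
                           max_epochs = config$epochs[[v$regime]],
                           seed = .fan_seed(config$seed, 4L))
        switch(v$regime,
               baseline = train_baseline(model, bundle, tc),
               overfit = train_overfit(model, bundle, tc),
               dp = train_dp(model, bundle, tc,
                             dp_config(target_epsilon = config$target_epsilon,
                                       delta = config$delta)))
      })
  }

  need_concepts <- any(c("concept", "gclm", "pclm") %in% config$feature_groups)
  ensembles <- NULL
  if (need_concepts) {
    ensembles <- lapply(victims, function(victim) {
      .cached_stage(config$out_dir, "explain",
                    list(.par_tree(victim$layers), gen_cfg), function() {
        arr <- as_image_array(bundle$concept)
        act <- .batched_activations(victim, arr$x, "gap")
        lapply(seq_len(gen_cfg$n_concepts), function(k)
          cav_ensemble(victim, "gap", bundle$concept, k, n = 100L,
                       activations = act))
      })
    })
  }

  scen <- lapply(config$scenarios, function(s)
    scenario_spec(s, config$n_per_side))
  results <- run_benchmark(victims, bundle, shifted_pool, scen,
                           feature_groups = config$feature_groups,
                           ensembles_by_victim = ensembles,
                           n_per_side = config$n_per_side,
                           seed = .fan_seed(config$seed, 5L),
                           progress = TRUE)
  export_results(results, config$out_dir)
  manifest$stages <- names(victims)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(results)
}
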