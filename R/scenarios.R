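# Deployment scenarios and the victim x regime x attack benchmark grid.

#' Deployment-scenario specification
#'
#' In the optimal deployment scenario the attacker's non-member pool comes
#' from the same distribution as training (the held-out test split); in the
#' suboptimal scenario it comes from a slightly shifted distribution,
#' emulating training data that under-covers the real-world population.
#' Members are always drawn from the victim's training split.
#'
#' @param name `"optimal"` or `"suboptimal"`.
#' @param n_per_side Members and non-members each.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name = c("optimal", "suboptimal"),
                          n_per_side = 500L) {
  name <- match.arg(name)
  structure(list(name = name, n_per_side = as.integer(n_per_side)),
            class = "scenario_spec")
}

#' Materialize the member / non-member sets of a scenario
#'
#' @param spec A [scenario_spec()].
#' @param bundle The victim's `dataset_bundle` (members come from its train
#'   split; optimal non-members from its test split).
#' @param shifted_pool List of `labeled_image` from the shifted distribution
#'   (required for the suboptimal scenario).
#' @param seed Sampling seed.
#' @return List with `members` and `nonmembers` (lists of `labeled_image`,
#'   each of length `n_per_side`).
#' @export
build_scenario <- function(spec, bundle, shifted_pool = NULL, seed = 0L) {
  stopifnot(inherits(spec, "scenario_spec"))
  pool_m <- bundle$train
  pool_n <- if (spec$name == "optimal") bundle$test else shifted_pool
  if (is.null(pool_n)) stop("suboptimal scenario needs a shifted pool")
  if (spec$n_per_side > length(pool_m) || spec$n_per_side > length(pool_n)) {
    stop(sprintf("n_per_side %d exceeds source sizes (%d members, %d non-members)",
                 spec$n_per_side, length(pool_m), length(pool_n)))
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(.fan_seed(seed, 5L)))
  list(members = pool_m[sample(length(pool_m), spec$n_per_side)],
       nonmembers = pool_n[sample(length(pool_n), spec$n_per_side)])
}

#' CAV quality report across training regimes
#'
#' Summarizes concept-classifier quality per regime: mean and standard
#' deviation of the CAV held-out accuracies over concepts (and members), and
#' the mean off-diagonal cosine similarity of each ensemble averaged over
#' concepts (1 = full alignment of the repeatedly trained CAVs, 0 =
#' orthogonality).
#'
#' @param ensembles_by_regime Named list: regime -> list of `cav_ensemble`.
#' @return data.frame with columns `regime`, `accuracy_mean`, `accuracy_std`,
#'   `mean_cosine`.
#' @export
cav_quality_report <- function(ensembles_by_regime) {
  if (!length(ensembles_by_regime)) stop("no ensembles supplied")
  rows <- lapply(names(ensembles_by_regime), function(rg) {
    ens <- ensembles_by_regime[[rg]]
    if (!length(ens)) stop("no ensembles for regime ", rg)
    accs <- unlist(lapply(ens, function(e)
      vapply(e$cavs, function(cv) cv$test_accuracy, numeric(1))))
    coss <- vapply(ens, function(e) {
      off <- e$cosine_matrix[upper.tri(e$cosine_matrix)]
      if (length(off)) mean(off) else 1
    }, numeric(1))
    data.frame(regime = rg, accuracy_mean = mean(accs),
               accuracy_std = stats::sd(accs), mean_cosine = mean(coss))
  })
  do.call(rbind, rows)
}

#' Run the full benchmark grid
#'
#' Executes every victim (arch x regime) x scenario x attack cell and
#' collects one result row per cell. Metric attacks contribute one row per
#' metric. Failures in a cell are recorded (column `error`) without aborting
#' the rest of the grid.
#'
#' @param victims Named list of trained `victim_model`s (name used in the
#'   output rows).
#' @param bundle The training `dataset_bundle`.
#' @param shifted_pool Shifted images for the suboptimal scenario.
#' @param scenarios List of [scenario_spec()].
#' @param feature_groups Character vector of feature groups to extract for
#'   metric attacks (see [extract_features()]).
#' @param attack_specs Optional list of [attack_vector_spec()] for
#'   classifier-based attacks (NULL = metric attacks only).
#' @param classifier_attacks Character subset of `c("svm", "fc", "cnn")`.
#' @param ensembles_by_victim Named list of CAV-ensemble lists (needed for
#'   concept feature groups).
#' @param n_per_side Scenario size.
#' @param seed Grid seed.
#' @param progress Print one line per cell.
#' @return data.frame with columns `arch`, `regime`, `scenario`, `attack`,
#'   `features`, `metric`, `value`, `n`, `seed`, `error`.
#' @export
run_benchmark <- function(victims, bundle, shifted_pool = NULL,
                          scenarios = list(scenario_spec("optimal")),
                          feature_groups = "prediction",
                          attack_specs = NULL,
                          classifier_attacks = character(0),
                          ensembles_by_victim = NULL,
                          n_per_side = 500L, seed = 0L, progress = FALSE) {
  rows <- list()
  note <- function(...) if (progress) cat(sprintf(...), "\n")
  for (vn in names(victims)) {
    victim <- victims[[vn]]
    ens <- ensembles_by_victim[[vn]]
    for (sc in scenarios) {
      sc$n_per_side <- min(sc$n_per_side, n_per_side)
      cell <- sprintf("%s/%s", vn, sc$name)
      res <- tryCatch({
        sets <- build_scenario(sc, bundle, shifted_pool, seed = seed)
        fm <- extract_features(victim, sets$members, ens, feature_groups)
        fn <- extract_features(victim, sets$nonmembers, ens, feature_groups)
        fb <- bind_features(fm, fn)
        out <- list()
        met <- metric_attack_suite(fb)
        for (i in seq_len(nrow(met))) {
          out[[length(out) + 1L]] <- data.frame(
            arch = victim$arch$family, regime = victim$regime,
            victim = vn, scenario = sc$name, attack = "metric",
            features = met$metric[i], metric = "auc", value = met$auc[i],
            n = 2L * sc$n_per_side, seed = seed, error = NA_character_)
        }
        for (spec in attack_specs) {
          for (ak in classifier_attacks) {
            ds <- assemble_attack_vector(
              fb, spec,
              split = if (ak == "svm") c(0.67, 0.33) else c(0.45, 0.22, 0.33),
              seed = seed)
            ar <- switch(ak,
              svm = svm_attack(ds, seed = seed),
              fc = nn_attack_fc(ds, seed = seed),
              cnn = nn_attack_cnn(ds, seed = seed))
            out[[length(out) + 1L]] <- data.frame(
              arch = victim$arch$family, regime = victim$regime,
              victim = vn, scenario = sc$name, attack = ak,
              features = ar$features, metric = ar$metric, value = ar$value,
              n = ar$n, seed = seed, error = NA_character_)
          }
        }
        note("cell %s: %d rows", cell, length(out))
        do.call(rbind, out)
      }, error = function(e) {
        warning(sprintf("cell %s failed: %s", cell, conditionMessage(e)),
                call. = FALSE)
        data.frame(arch = victim$arch$family,
                   regime = if (is.null(victim$regime)) NA_character_ else victim$regime,
                   victim = vn, scenario = sc$name, attack = NA_character_,
                   features = NA_character_, metric = NA_character_,
                   value = NA_real_, n = NA_integer_, seed = seed,
                   error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Export benchmark results
#'
#' Writes the canonical results CSV, a per-(scenario, attack) summary JSON,
#' and optional bar-chart PNGs of metric-attack AUCs per scenario.
#'
#' @param results data.frame from [run_benchmark()].
#' @param directory Output directory.
#' @param charts Also render bar charts.
#' @return Invisible character vector of written files.
#' @export
export_results <- function(results, directory, charts = FALSE) {
  if (is.null(results) || !nrow(results)) stop("no results to export")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(directory, "results.csv")
  utils::write.csv(results, files[1], row.names = FALSE)
  ok <- results[is.na(results$error), , drop = FALSE]
  summ <- list()
  for (scn in unique(ok$scenario)) {
    for (atk in unique(ok$attack[ok$scenario == scn])) {
      sel <- ok$scenario == scn & ok$attack == atk
      summ[[paste(scn, atk, sep = ".")]] <- list(
        scenario = scn, attack = atk, n_cells = sum(sel),
        mean_value = mean(ok$value[sel]), max_value = max(ok$value[sel]))
    }
  }
  jf <- file.path(directory, "summary.json")
  jsonlite::write_json(summ, jf, auto_unbox = TRUE, digits = NA)
  files <- c(files, jf)
  if (charts) {
    for (scn in unique(ok$scenario)) {
      sel <- ok$scenario == scn & ok$attack == "metric"
      if (!any(sel)) next
      pf <- file.path(directory, paste0("metric_auc_", scn, ".png"))
      grDevices::png(pf, width = 900, height = 480)
      graphics::par(mar = c(10, 4, 2, 1))
      graphics::barplot(ok$value[sel],
                        names.arg = paste(ok$victim[sel], ok$features[sel]),
                        las = 2, ylim = c(0, 100), ylab = "AUC (%)",
                        main = paste("metric attacks,", scn, "scenario"))
      graphics::abline(h = 50, lty = 2)
      grDevices::dev.off()
      files <- c(files, pf)
    }
  }
  invisible(files)
}
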