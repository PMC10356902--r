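#' Generate the full synthetic dataset bundle
#'
#' Produces the four portions of the benchmark — train, validation, test and
#' a separate concept-learning portion — with disjoint sample ids. Under the
#' default configuration the portion sizes are 4,800 / 1,200 / 1,500 / 6,000.
#' The bundle is a pure function of the configuration (including its seed).
#'
#' @param config A [generator_config()].
#' @param progress Print a dot every 500 images.
#' @return A `dataset_bundle`: list with `train`, `val`, `test`, `concept`
#'   lists of `labeled_image` and the `config` as provenance.
#' @export
generate_dataset <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  portions <- names(config$split_sizes)
  out <- list()
  idx <- 0L
  for (p in portions) {
    n <- config$split_sizes[[p]]
    imgs <- vector("list", n)
    for (i in seq_len(n)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%06d", p, i)
      imgs[[i]] <- generate_image(config, seed = .fan_seed(config$seed, 1L, idx),
                                  sample_id = sid)
      if (progress && idx %% 500L == 0L) cat(".")
    }
    out[[p]] <- imgs
  }
  if (progress) cat("\n")
  structure(list(train = out$train, val = out$val, test = out$test,
                 concept = out$concept, config = config),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("<dataset_bundle>", length(x$train), "train /", length(x$val), "val /",
      length(x$test), "test /", length(x$concept), "concept,",
      x$config$image_size, "px\n")
  invisible(x)
}

#' Stack a list of labeled images into arrays
#'
#' @param imgs List of `labeled_image`.
#' @return List with `x` (H x W x 3 x N array), `y` (integer labels 0/1),
#'   `presence` (N x K matrix), `ids` (character).
#' @export
as_image_array <- function(imgs) {
  n <- length(imgs)
  stopifnot(n > 0L)
  S <- imgs[[1]]$image_size
  x <- array(0, c(S, S, 3, n))
  for (i in seq_len(n)) x[, , , i] <- imgs[[i]]$pixels
  y <- vapply(imgs, function(im) im$class_label, integer(1))
  presence <- do.call(rbind, lapply(imgs, function(im) im$concept_presence))
  ids <- vapply(imgs, function(im) im$sample_id, "")
  list(x = x, y = y, presence = presence, ids = ids)
}

#' Write a dataset bundle to disk
#'
#' Images are written as 8-bit RGB PNG (`<sample_id>.png`), masks as 8-bit
#' grayscale PNG with values 0/255 (`<sample_id>_c<k>.png`, `k` 0-based),
#' per-sample metadata as a single CSV (`metadata.csv` with columns
#' `sample_id,split,class,presence_0..presence_{K-1}`) and the provenance
#' configuration as YAML (`config.yaml`; the class rule is recorded by its
#' id).
#'
#' @param bundle A `dataset_bundle`.
#' @param directory Output directory (created if missing).
#' @param masks Also write the per-concept mask PNGs.
#' @return `directory`, invisibly.
#' @export
write_dataset <- function(bundle, directory, masks = TRUE) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  K <- bundle$config$n_concepts
  rows <- list()
  for (split in c("train", "val", "test", "concept")) {
    for (im in bundle[[split]]) {
      png::writePNG(im$pixels, file.path(directory, paste0(im$sample_id, ".png")))
      if (masks) {
        for (k in seq_len(K)) {
          png::writePNG(concept_mask(im, k),
                        file.path(directory, sprintf("%s_c%d.png", im$sample_id, k - 1L)))
        }
      }
      rows[[length(rows) + 1L]] <- c(sample_id = im$sample_id, split = split,
                                     class = im$class_label, im$concept_presence)
    }
  }
  meta <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(meta) <- c("sample_id", "split", "class",
                   paste0("presence_", seq_len(K) - 1L))
  utils::write.csv(meta, file.path(directory, "metadata.csv"), row.names = FALSE)
  cfg <- bundle$config
  prov <- list(image_size = cfg$image_size,
               n_concepts = cfg$n_concepts,
               class_rule_id = cfg$class_rule_id,
               class_rule_note = "stand-in rule; resolution/concept count are package defaults",
               split_sizes = as.list(cfg$split_sizes),
               presence_prob = cfg$presence_prob,
               noise_sigma = cfg$noise_sigma,
               shift = unclass(cfg$shift),
               seed = cfg$seed,
               concepts = lapply(cfg$concepts, function(cs) {
                 list(concept_id = cs$concept_id, shape_family = cs$shape_family,
                      size_range = cs$size_range,
                      color_low = unname(cs$color_range[, 1]),
                      color_high = unname(cs$color_range[, 2]),
                      count_range = cs$count_range)
               }))
  yaml::write_yaml(prov, file.path(directory, "config.yaml"))
  invisible(directory)
}

#' Read a dataset bundle from disk
#'
#' Reconstructs the bundle written by [write_dataset()]. Labels and presence
#' bits round-trip exactly; pixels round-trip within 8-bit PNG quantization.
#'
#' @param directory Directory written by [write_dataset()].
#' @return A `dataset_bundle` (its `config` is rebuilt from `config.yaml`;
#'   a non-default class rule id yields a rule that refuses evaluation).
#' @export
read_dataset <- function(directory) {
  meta_path <- file.path(directory, "metadata.csv")
  if (!file.exists(meta_path)) stop("missing metadata.csv in ", directory)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  prov <- yaml::read_yaml(file.path(directory, "config.yaml"))
  K <- prov$n_concepts
  rule <- if (identical(prov$class_rule_id, "default-v1")) default_class_rule else
    function(presence) stop("unknown class rule id: ", prov$class_rule_id)
  cfg <- generator_config(image_size = prov$image_size,
                          class_rule = rule,
                          class_rule_id = prov$class_rule_id,
                          split_sizes = unlist(prov$split_sizes),
                          presence_prob = prov$presence_prob,
                          noise_sigma = prov$noise_sigma,
                          shift = do.call(shift_config, prov$shift),
                          seed = prov$seed)
  fams <- vapply(cfg$concepts, function(cc) cc$shape_family, "")
  out <- list(train = list(), val = list(), test = list(), concept = list())
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    img_path <- file.path(directory, paste0(sid, ".png"))
    if (!file.exists(img_path)) stop("missing image file for sample ", sid)
    px <- png::readPNG(img_path)
    S <- dim(px)[1]
    presence <- as.integer(meta[i, paste0("presence_", seq_len(K) - 1L)])
    names(presence) <- fams
    masks <- vector("list", K)
    for (k in seq_len(K)) {
      mp <- file.path(directory, sprintf("%s_c%d.png", sid, k - 1L))
      masks[[k]] <- if (file.exists(mp)) which(png::readPNG(mp) > 0.5) else integer(0)
    }
    im <- structure(list(pixels = px,
                         class_label = as.integer(meta$class[i]),
                         concept_presence = presence,
                         concept_mask_idx = masks,
                         sample_id = sid,
                         image_size = S),
                    class = "labeled_image")
    out[[meta$split[i]]][[length(out[[meta$split[i]]]) + 1L]] <- im
  }
  structure(list(train = out$train, val = out$val, test = out$test,
                 concept = out$concept, config = cfg),
            class = "dataset_bundle")
}

.pool_matrix <- function(S, f) {
  S2 <- S %/% f
  P <- matrix(0, S, S2)
  P[cbind(seq_len(S2 * f), rep(seq_len(S2), each = f))] <- 1 / f
  P
}

.downsample_pixels <- function(px, f) {
  d <- dim(px)
  Ph <- .pool_matrix(d[1], f); Pw <- .pool_matrix(d[2], f)
  out <- array(0, c(ncol(Ph), ncol(Pw), d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- crossprod(Ph, px[, , ch] %*% Pw)
  out
}

#' Reduce the resolution of labeled images by mean pooling
#'
#' Downsamples pixels by an integer factor with f x f mean pooling; a
#' downsampled mask cell is foreground when any covered source pixel is.
#'
#' @param imgs List of `labeled_image`, or a `dataset_bundle`.
#' @param factor Integer pooling factor.
#' @return The same structure at reduced resolution.
#' @export
downsample_images <- function(imgs, factor = 2L) {
  f <- as.integer(factor)
  if (inherits(imgs, "dataset_bundle")) {
    for (p in c("train", "val", "test", "concept")) {
      imgs[[p]] <- downsample_images(imgs[[p]], f)
    }
    imgs$config$image_size <- imgs$config$image_size %/% f
    return(imgs)
  }
  lapply(imgs, function(im) {
    S <- im$image_size
    S2 <- S %/% f
    im$pixels <- .downsample_pixels(im$pixels, f)
    im$concept_mask_idx <- lapply(im$concept_mask_idx, function(idx) {
      if (!length(idx)) return(integer(0))
      r2 <- ((idx - 1L) %% S) %/% f
      c2 <- ((idx - 1L) %/% S) %/% f
      keep <- r2 < S2 & c2 < S2
      sort(unique(r2[keep] + c2[keep] * S2 + 1L))
    })
    im$image_size <- S2
    im
  })
}
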