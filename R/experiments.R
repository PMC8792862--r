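# Experiment protocols on in-memory radiograph sets. Phantom lists are
# referenced through manifests whose image/mask fields hold the image_id;
# load_entries() resolves them against the `images` list, so the same code
# paths serve on-disk datasets and in-memory phantoms.

rads_to_manifest <- function(rads, pool = "annotated") {
  ids <- vapply(rads, function(r) r$image_id, "")
  masked <- vapply(rads, function(r) !is.null(r$mask), TRUE)
  # a mask-less entry cannot sit in a pool that requires annotations
  pools <- rep(pool, length(rads))
  pools[!masked] <- if (pool == "source") "target" else "unannotated"
  data.frame(image = ids, mask = ifelse(masked, ids, ""),
             pool = pools, fold = NA_integer_, stringsAsFactors = FALSE)
}

rads_by_id <- function(rads) {
  setNames(rads, vapply(rads, function(r) r$image_id, ""))
}

set_mode <- function(config, mode) {
  config$mode <- mode
  if (mode == "supervised") config$use_generator <- FALSE
  config
}

#' Semi-supervised annotation-fraction experiment
#'
#' For each annotated fraction, trains the requested modes and evaluates
#' Dice and Jaccard on held-out images. With `k_folds >= 2` the protocol is
#' k-fold cross-validation; with `k_folds = 1` a single holdout split
#' (`holdout_fraction` of the images reserved for testing) is used, which
#' pairs modes on identical training/test images — the layout used when
#' comparing modes seed by seed.
#'
#' @param config a [train_config()]; its mode is overridden per arm.
#' @param phantoms list of [radiograph()]s with masks.
#' @param fractions annotated fractions in `(0, 1]`.
#' @param k_folds folds (>= 2), or 1 for a single holdout split.
#' @param modes training modes to run per fraction.
#' @param holdout_fraction test fraction when `k_folds = 1`.
#' @return data.frame with one row per (fraction, mode, fold): mean and sd
#'   of Dice and Jaccard over the held-out images.
#' @export
run_semisup_experiment <- function(config, phantoms,
                                   fractions = c(0.125, 0.25, 0.5, 1),
                                   k_folds = 5L,
                                   modes = "semi_supervised",
                                   holdout_fraction = 0.3) {
  if (any(fractions <= 0 | fractions > 1))
    stop_validation("fractions must lie in (0, 1]")
  images <- rads_by_id(phantoms)
  manifest <- rads_to_manifest(phantoms)
  n <- nrow(manifest)
  rows <- list()
  for (frac in fractions) {
    if (k_folds >= 2L) {
      m <- make_semisup_splits(manifest, frac, k_folds, config$seed)
      folds <- seq_len(k_folds)
    } else {
      m <- manifest
      with_seed(config$seed, {
        test_idx <- sample.int(n, round(holdout_fraction * n))
        m$fold <- 1L
        m$fold[test_idx] <- 0L           # fold 0 = the holdout test set
        train_idx <- which(m$fold == 1L)
        ann <- sample(train_idx, ceiling(frac * length(train_idx)))
        m$pool <- "unannotated"
        m$pool[ann] <- "annotated"
      })
      folds <- 0L
    }
    for (f in folds) {
      train_m <- m[m$fold != f, , drop = FALSE]
      test_ids <- m$image[m$fold == f]
      for (mode in modes) {
        cfg <- set_mode(config, mode)
        state <- train(cfg, train_m, images = images)
        ev <- evaluate_rads(state$disc, images[test_ids])
        rows[[length(rows) + 1L]] <- data.frame(
          fraction = frac, mode = mode, fold = f,
          dice = ev["dice"], sd_dice = ev["sd_dice"],
          jaccard = ev["jaccard"], sd_jaccard = ev["sd_jaccard"],
          row.names = NULL)
      }
    }
  }
  do.call(rbind, rows)
}

#' Unsupervised domain adaptation experiment
#'
#' Splits both domains (default 7:1:2 train/val/test), trains two arms —
#' supervised on the annotated source training images, and the
#' domain-adaptation mode on annotated source plus unannotated target
#' training images — and reports four evaluations: the source-trained model
#' on the source test set (`sup_source`) and on the target test set with no
#' adaptation (`t_noda`), and the adapted model on the target (`uda_target`)
#' and source (`s_test`) test sets.
#'
#' @param config a [train_config()].
#' @param source list of masked [radiograph()]s from the annotated domain.
#' @param target list of masked [radiograph()]s from the shifted domain
#'   (masks are used for evaluation only).
#' @param ratios train/val/test ratios.
#' @return data.frame with columns arm, domain, dice, sd_dice, jaccard,
#'   sd_jaccard.
#' @export
run_uda_experiment <- function(config, source, target,
                               ratios = c(0.7, 0.1, 0.2)) {
  # namespace the ids so identically named phantoms from the two domains
  # cannot shadow each other in the lookup table
  source <- lapply(source, function(r) {
    r$image_id <- paste0("src_", r$image_id); r
  })
  target <- lapply(target, function(r) {
    r$image_id <- paste0("tgt_", r$image_id); r
  })
  images <- c(rads_by_id(source), rads_by_id(target))
  sm <- rads_to_manifest(source, "source")
  tm <- rads_to_manifest(target, "target")
  m <- make_uda_splits(sm, tm, ratios, config$seed)

  train_m <- m[m$split == "train", , drop = FALSE]
  src_test <- m$image[m$pool == "source" & m$split == "test"]
  tgt_test <- m$image[m$pool == "target" & m$split == "test"]

  sup_cfg <- set_mode(config, "supervised")
  sup_state <- train(sup_cfg,
                     train_m[train_m$pool == "source", , drop = FALSE],
                     images = images)
  uda_cfg <- set_mode(config, "uda")
  uda_state <- train(uda_cfg, train_m, images = images)

  evs <- list(
    sup_source = list(sup_state$disc, src_test, "source"),
    t_noda = list(sup_state$disc, tgt_test, "target"),
    uda_target = list(uda_state$disc, tgt_test, "target"),
    s_test = list(uda_state$disc, src_test, "source"))
  rows <- lapply(names(evs), function(a) {
    e <- evs[[a]]
    ev <- evaluate_rads(e[[1]], images[e[[2]]])
    data.frame(arm = a, domain = e[[3]], dice = ev["dice"],
               sd_dice = ev["sd_dice"], jaccard = ev["jaccard"],
               sd_jaccard = ev["sd_jaccard"], row.names = NULL)
  })
  do.call(rbind, rows)
}
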