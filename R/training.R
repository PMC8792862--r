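#' Training configuration
#'
#' Alternating adversarial optimisation settings. The reference protocol is
#' 500 epochs at 1024 x 1024 with a ResNet-50-style encoder, Adam rates
#' 0.001 (generator) and 0.0001 (discriminator), both multiplied by 0.1
#' after epoch 200; [full_scale_config()] selects it. The default desk-scale
#' schedule compresses this to 30 epochs at resolution 64 with the
#' small-cnn encoder so it trains in minutes on one CPU: the decay point
#' keeps its 40%-of-schedule position and the learning rates are scaled up
#' tenfold to compensate for the roughly sixteenfold shorter schedule
#' (Adam's per-step displacement is rate-bound, so total displacement is
#' approximately rate x steps).
#'
#' @param mode `"supervised"` (annotated pool only, no generator),
#'   `"semi_supervised"` (annotated + unannotated + generated, pixel-level
#'   loss), `"original_gan"` (image-level adversarial head ablation) or
#'   `"uda"` (source pool plays annotated, target plays unannotated).
#' @param epochs number of joint generator/discriminator epochs.
#' @param lr_generator,lr_discriminator initial Adam learning rates.
#' @param lr_decay_factor multiplier applied after `lr_decay_epoch`.
#' @param lr_decay_epoch epoch after which rates decay; default 40% of
#'   `epochs`.
#' @param batch_size images per pool per iteration.
#' @param resolution input image side length.
#' @param seed seed controlling weight init, batching and noise.
#' @param generator_spec,discriminator_spec network specs; sensible
#'   desk-scale defaults are derived from `resolution` when `NULL`.
#' @param use_generator logical; the supervised mode forces this off.
#' @param nonsaturating_generator use the non-saturating generator loss.
#' @param checkpoint_every write a checkpoint every this many epochs (only
#'   when `out_dir` is set).
#' @param out_dir optional directory for `losses.csv` and checkpoints.
#' @return an object of class `usgan_train_config`.
#' @export
train_config <- function(mode = c("semi_supervised", "supervised",
                                  "original_gan", "uda"),
                         epochs = 30L, lr_generator = 0.01,
                         lr_discriminator = 0.001, lr_decay_factor = 0.1,
                         lr_decay_epoch = NULL, batch_size = 16L,
                         resolution = 64L, seed = 1L,
                         generator_spec = NULL, discriminator_spec = NULL,
                         use_generator = TRUE,
                         nonsaturating_generator = FALSE,
                         checkpoint_every = 10L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (lr_generator <= 0 || lr_discriminator <= 0)
    stop_validation("learning rates must be > 0")
  if (is.null(lr_decay_epoch)) lr_decay_epoch <- ceiling(0.4 * epochs)
  if (lr_decay_epoch >= epochs && epochs > 1L)
    stop_validation("lr_decay_epoch must be < epochs")
  if (mode == "supervised") use_generator <- FALSE
  if (is.null(generator_spec) && use_generator) {
    B <- max(1L, as.integer(floor(log(resolution / 4) / log(4))))
    base <- resolution %/% 4L^B
    if (base * 4L^B != resolution)
      stop_validation(
        "no default generator for resolution %d (need base * 4^B); pass generator_spec",
        resolution)
    cs <- as.integer(64 / 2^(0:B))
    generator_spec <- generator_spec(output_resolution = resolution,
                                     channel_schedule = cs,
                                     base_resolution = base)
  }
  if (is.null(discriminator_spec)) {
    discriminator_spec <- discriminator_spec(
      encoder = "small-cnn", input_resolution = resolution,
      n_classes = if (mode == "original_gan") 2L else 3L,
      cls_head = mode == "original_gan")
  }
  if (mode == "original_gan" &&
      (!discriminator_spec$cls_head || discriminator_spec$n_classes != 2L))
    stop_validation(
      "original_gan mode needs a 2-class discriminator with cls_head = TRUE")
  structure(list(mode = mode, epochs = as.integer(epochs),
                 lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_epoch = as.integer(lr_decay_epoch),
                 batch_size = as.integer(batch_size),
                 resolution = as.integer(resolution),
                 seed = as.integer(seed),
                 generator_spec = generator_spec,
                 discriminator_spec = discriminator_spec,
                 use_generator = use_generator,
                 nonsaturating_generator = isTRUE(nonsaturating_generator),
                 checkpoint_every = as.integer(checkpoint_every),
                 out_dir = out_dir),
            class = "usgan_train_config")
}

#' Full-protocol configuration preset
#'
#' The full training protocol: 500 epochs at 1024 x 1024, ResNet-50-style
#' encoder, learning-rate decay after epoch 200.
#'
#' @inheritParams train_config
#' @param ... passed on to [train_config()].
#' @export
full_scale_config <- function(mode = "semi_supervised", ...) {
  train_config(mode = mode, epochs = 500L, lr_decay_epoch = 200L,
               lr_generator = 0.001, lr_discriminator = 0.0001,
               resolution = 1024L,
               generator_spec = generator_spec(output_resolution = 1024L),
               discriminator_spec = discriminator_spec(
                 encoder = "resnet50", input_resolution = 1024L), ...)
}

current_lr <- function(initial, epoch, config) {
  if (epoch > config$lr_decay_epoch) initial * config$lr_decay_factor
  else initial
}

stack_images <- function(rads, idx) {
  r1 <- rads[[idx[1]]]$pixels
  out <- array(0, c(nrow(r1), ncol(r1), 1L, length(idx)))
  for (i in seq_along(idx)) out[, , 1L, i] <- rads[[idx[i]]]$pixels
  out
}

stack_masks <- function(rads, idx) {
  r1 <- rads[[idx[1]]]$mask
  out <- array(0, c(nrow(r1), ncol(r1), length(idx)))
  for (i in seq_along(idx)) out[, , i] <- rads[[idx[i]]]$mask
  out
}

check_finite <- function(losses, epoch, it, batches) {
  bad <- !vapply(losses, is.finite, TRUE)
  if (any(bad)) {
    stats <- vapply(batches, function(b)
      if (is.null(b)) NA_real_ else mean(b), 0)
    stop(sprintf(
      "non-finite loss (%s) at epoch %d iteration %d; batch means: %s",
      paste(names(losses)[bad], collapse = ", "), epoch, it,
      paste(sprintf("%s=%.4g", names(stats), stats), collapse = ", ")))
  }
}

select_pools <- function(config, manifest, images) {
  validate_manifest(manifest)
  if ("split" %in% names(manifest) && any(manifest$split == "train"))
    manifest <- manifest[manifest$split == "train", , drop = FALSE]
  if (config$mode == "uda") {
    ann <- manifest[manifest$pool == "source", , drop = FALSE]
    un <- manifest[manifest$pool == "target", , drop = FALSE]
  } else {
    ann <- manifest[manifest$pool %in% c("annotated", "source"), , drop = FALSE]
    un <- manifest[manifest$pool %in% c("unannotated", "target"), , drop = FALSE]
  }
  if (nrow(ann) == 0L)
    stop_validation("mode '%s' requires a nonempty annotated/source pool",
                    config$mode)
  if (config$mode %in% c("semi_supervised", "uda", "original_gan") &&
      nrow(un) == 0L && config$mode == "uda")
    stop_validation("uda mode requires a nonempty target pool")
  ann_rads <- load_entries(ann, config$resolution, images, with_masks = TRUE)
  no_mask <- vapply(ann_rads, function(r) is.null(r$mask), TRUE)
  if (any(no_mask))
    stop_validation("%d annotated/source entries lack masks", sum(no_mask))
  un_rads <- if (nrow(un) > 0L)
    load_entries(un, config$resolution, images, with_masks = FALSE)
  else list()
  list(annotated = ann_rads, unannotated = un_rads)
}

#' Train the adversarial segmentation model
#'
#' Runs the alternating optimisation: each iteration samples an annotated
#' batch, an unannotated batch (if the mode uses one) and a noise batch,
#' takes one Adam step on the discriminator loss, then one on the generator
#' loss. An epoch is one pass over the larger pool, sampling the smaller
#' pool with replacement. The run is a pure function of the configuration
#' (including its seed) and the data.
#'
#' @param config a [train_config()].
#' @param manifest manifest data.frame describing the training pools.
#' @param images optional named list of in-memory [radiograph()]s keyed by
#'   the manifest image column.
#' @param resume optional path to a checkpoint; training continues from its
#'   epoch with bitwise-identical trajectory to an uninterrupted run.
#' @return an object of class `usgan_train_state`: list with the trained
#'   `gen` and `disc`, optimiser states, `loss_history` data.frame (one row
#'   per epoch: L_l, L_u, L_g, L_D, L_G, learning rates) and `config`.
#' @export
train <- function(config, manifest, images = NULL, resume = NULL) {
  stopifnot(inherits(config, "usgan_train_config"))
  pools <- select_pools(config, manifest, images)
  ann <- pools$annotated
  un <- pools$unannotated
  use_un <- config$mode != "supervised" && length(un) > 0L
  use_gen <- config$use_generator

  if (!is.null(resume)) {
    ck <- readRDS(resume)
    gen <- ck$gen; disc <- ck$disc
    ad_g <- ck$adam_g; ad_d <- ck$adam_d
    start_epoch <- ck$epoch + 1L
    history <- ck$loss_history
    assign(".Random.seed", ck$rng, envir = globalenv())
  } else {
    set.seed(config$seed)
    gen <- if (use_gen) build_generator(config$generator_spec) else NULL
    disc <- build_discriminator(config$discriminator_spec)
    ad_g <- if (use_gen) adam_init(gen$params) else NULL
    ad_d <- adam_init(disc$params)
    start_epoch <- 1L
    history <- NULL
  }

  nb <- config$batch_size
  n_larger <- max(length(ann), if (use_un) length(un) else 0L)
  iters <- max(1L, ceiling(n_larger / nb))
  sample_batch <- function(n) sample.int(n, nb, replace = nb > n)
  original <- config$mode == "original_gan"

  for (epoch in seq(start_epoch, length.out = max(0L, config$epochs - start_epoch + 1L))) {
    lr_d <- current_lr(config$lr_discriminator, epoch, config)
    lr_g <- current_lr(config$lr_generator, epoch, config)
    ep <- c(L_l = 0, L_u = 0, L_g = 0, L_D = 0, L_G = 0)
    for (it in seq_len(iters)) {
      ia <- sample_batch(length(ann))
      xb <- stack_images(ann, ia)
      mb <- stack_masks(ann, ia)
      xu <- if (use_un) stack_images(un, sample_batch(length(un))) else NULL
      xf <- if (use_gen)
        generator_forward(gen, sample_noise(nb, gen$spec$noise_dim))$out
      else NULL

      # one concatenated discriminator pass over all pools; each pool's
      # per-pixel mean gradient occupies its own slice of the batch, so the
      # result is identical to three separate passes with summed gradients
      seg_ann <- seq_len(nb)
      seg_un <- if (use_un) nb + seq_len(nb) else integer(0)
      seg_fake <- if (use_gen) nb + length(seg_un) + seq_len(nb) else integer(0)
      ntot <- nb + length(seg_un) + length(seg_fake)
      res <- config$resolution
      xall <- array(c(xb, xu, xf), c(res, res, 1L, ntot))
      fall <- discriminator_forward(disc, xall, train = TRUE)
      garr <- array(0, dim(fall$logits))
      pa <- fall$probs[, , , seg_ann, drop = FALSE]
      gcls <- NULL
      if (original) {
        L_l <- supervised_loss_2class(pa, mb)
        garr[, , , seg_ann] <- grad_supervised_2class(pa, mb)
        pr <- 1 / (1 + exp(-fall$cls))
        y_cls <- as.numeric(seq_len(ntot) %in% c(seg_ann, seg_un))
        L_u <- -mean(safe_log(pr[c(seg_ann, seg_un)]))
        L_g <- if (use_gen) -mean(safe_log(1 - pr[seg_fake])) else 0
        gcls <- (pr - y_cls) / ntot
      } else {
        L_l <- supervised_loss(pa, mb)
        garr[, , , seg_ann] <- grad_supervised(pa, mb)
        L_u <- 0; L_g <- 0
        if (use_un) {
          pu <- fall$probs[, , , seg_un, drop = FALSE]
          L_u <- unsupervised_real_loss(pu)
          garr[, , , seg_un] <- grad_unsupervised_real(pu)
        }
        if (use_gen) {
          pf <- fall$probs[, , , seg_fake, drop = FALSE]
          L_g <- fake_loss(pf)
          garr[, , , seg_fake] <- grad_fake(pf)
        }
      }
      L_D <- L_l + L_u + L_g
      check_finite(list(L_l = L_l, L_u = L_u, L_g = L_g), epoch, it,
                   list(annotated = xb, unannotated = xu, generated = xf))
      bw <- discriminator_backward(disc, fall$cache, garr, gcls = gcls)
      grads <- bw$grads
      miss <- setdiff(names(disc$params), names(grads))
      for (nm in miss) grads[[nm]] <- disc$params[[nm]] * 0
      st <- adam_step(disc$params, grads[names(disc$params)], ad_d, lr_d)
      disc$params <- st$params; ad_d <- st$state

      L_G <- 0
      if (use_gen) {
        zg <- sample_noise(nb, gen$spec$noise_dim)
        gf <- generator_forward(gen, zg, train = TRUE)
        fg <- discriminator_forward(disc, gf$out, train = TRUE)
        if (original) {
          pr <- 1 / (1 + exp(-fg$cls))
          L_G <- mean(safe_log(1 - pr))
          gcls <- -pr / nb
          zero_seg <- array(0, dim(fg$logits))
          bw <- discriminator_backward(disc, fg$cache, zero_seg, gcls = gcls,
                                       want_gx = TRUE)
        } else {
          L_G <- generator_loss(fg$probs, config$nonsaturating_generator)
          bw <- discriminator_backward(
            disc, fg$cache,
            grad_generator(fg$probs, config$nonsaturating_generator),
            want_gx = TRUE)
        }
        check_finite(list(L_G = L_G), epoch, it, list(generated = gf$out))
        gg <- generator_backward(gen, gf$cache, bw$gx)
        miss <- setdiff(names(gen$params), names(gg))
        for (nm in miss) gg[[nm]] <- gen$params[[nm]] * 0
        st <- adam_step(gen$params, gg[names(gen$params)], ad_g, lr_g)
        gen$params <- st$params; ad_g <- st$state
      }
      ep <- ep + c(L_l, L_u, L_g, L_D, L_G)
    }
    row <- data.frame(epoch = epoch, L_l = ep[1] / iters, L_u = ep[2] / iters,
                      L_g = ep[3] / iters, L_D = ep[4] / iters,
                      L_G = ep[5] / iters, lr_d = lr_d, lr_g = lr_g)
    history <- rbind(history, row)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write.csv(history, file.path(config$out_dir, "losses.csv"),
                row.names = FALSE)
      if (epoch %% config$checkpoint_every == 0L || epoch == config$epochs) {
        save_checkpoint(list(epoch = epoch, gen = gen, disc = disc,
                             adam_g = ad_g, adam_d = ad_d,
                             rng = get(".Random.seed", envir = globalenv()),
                             loss_history = history, config = config),
                        file.path(config$out_dir,
                                  sprintf("checkpoint_%03d.rds", epoch)))
      }
    }
  }
  structure(list(gen = gen, disc = disc, adam_g = ad_g, adam_d = ad_d,
                 epoch = config$epochs, loss_history = history,
                 config = config),
            class = "usgan_train_state")
}

#' Save a self-describing checkpoint
#'
#' The checkpoint archives the weights together with the full
#' configuration, its network specs rendered as embedded JSON, and the RNG
#' state, so training can resume with a bitwise-identical trajectory.
#'
#' @param state a checkpoint list or `usgan_train_state`.
#' @param path output path (RDS).
#' @export
save_checkpoint <- function(state, path) {
  state$spec_json <- jsonlite::toJSON(
    list(mode = state$config$mode,
         generator = unclass(state$config$generator_spec),
         discriminator = unclass(state$config$discriminator_spec)),
    auto_unbox = TRUE, null = "null")
  saveRDS(state, path)
  invisible(path)
}

#' Load a checkpoint
#' @param path checkpoint path written by [save_checkpoint()] or [train()].
#' @return the checkpoint list.
#' @export
load_checkpoint <- function(path) readRDS(path)
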