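# Training-loop behaviour on tiny problems: decreasing supervised loss,
# mode algebra, the learning-rate schedule, determinism and resume.

tiny_train_config <- function(mode = "supervised", epochs = 2L, seed = 7L,
                              ...) {
  train_config(mode = mode, epochs = epochs, seed = seed, resolution = 32L,
               batch_size = 4L, lr_decay_epoch = max(1L, epochs - 1L),
               generator_spec = generator_spec(32L,
                                               channel_schedule = c(8L, 4L),
                                               base_resolution = 8L),
               discriminator_spec = tiny_disc_spec(
                 32L, n_classes = if (mode == "original_gan") 2L else 3L,
                 cls_head = mode == "original_gan"), ...)
}

tiny_set <- function(n = 8, seed = 3) {
  generate_phantoms(phantom_config(resolution = 32, n_images = n, seed = seed))
}

ns <- asNamespace("usgan")

test_that("supervised training reduces the supervised loss", {
  ph <- tiny_set(8)
  cfg <- tiny_train_config("supervised", epochs = 3L)
  st <- train(cfg, ns$rads_to_manifest(ph), images = ns$rads_by_id(ph))
  h <- st$loss_history
  expect_equal(nrow(h), 3)
  expect_lt(h$L_l[3], h$L_l[1])
  expect_true(all(h$L_u == 0) && all(h$L_g == 0))
})

test_that("semi-supervised mode with no unannotated data and no generator
           reduces exactly to supervised training", {
  ph <- tiny_set(8)
  m <- ns$rads_to_manifest(ph)
  cfg_sup <- tiny_train_config("supervised")
  cfg_semi <- tiny_train_config("semi_supervised", use_generator = FALSE)
  st_sup <- train(cfg_sup, m, images = ns$rads_by_id(ph))
  st_semi <- train(cfg_semi, m, images = ns$rads_by_id(ph))
  expect_identical(st_sup$loss_history$L_l, st_semi$loss_history$L_l)
  expect_identical(st_sup$disc$params, st_semi$disc$params)
})

test_that("learning rates decay by the configured factor after the decay epoch", {
  ph <- tiny_set(6)
  cfg <- tiny_train_config("supervised", epochs = 3L)  # decay after epoch 2
  st <- train(cfg, ns$rads_to_manifest(ph), images = ns$rads_by_id(ph))
  h <- st$loss_history
  expect_equal(h$lr_d[1], cfg$lr_discriminator)
  expect_equal(h$lr_d[3], cfg$lr_discriminator * 0.1)
  expect_equal(h$lr_g[3], cfg$lr_generator * 0.1)
})

test_that("adversarial training runs in every mode and logs all loss terms", {
  ph <- tiny_set(8)
  m <- ns$rads_to_manifest(ph)
  m$pool[5:8] <- "unannotated"
  m$mask[5:8] <- ""
  for (mode in c("semi_supervised", "original_gan")) {
    cfg <- tiny_train_config(mode, epochs = 1L)
    st <- train(cfg, m, images = ns$rads_by_id(ph))
    h <- st$loss_history
    expect_true(all(is.finite(unlist(h[, c("L_l", "L_u", "L_g", "L_D", "L_G")]))))
    expect_gt(h$L_u[1], 0)
  }
  # uda mode consumes source/target pools
  mu <- ns$rads_to_manifest(ph)
  mu$pool <- rep(c("source", "target"), each = 4)
  cfg <- tiny_train_config("uda", epochs = 1L)
  st <- train(cfg, mu, images = ns$rads_by_id(ph))
  expect_true(is.finite(st$loss_history$L_D[1]))
  expect_error(train(cfg, mu[mu$pool == "source", , drop = FALSE],
                     images = ns$rads_by_id(ph)),
               class = "usgan_validation_error")
})

test_that("identical configurations yield bitwise-identical trajectories", {
  ph <- tiny_set(6)
  m <- ns$rads_to_manifest(ph)
  m$pool[4:6] <- "unannotated"; m$mask[4:6] <- ""
  cfg <- tiny_train_config("semi_supervised", epochs = 2L)
  a <- train(cfg, m, images = ns$rads_by_id(ph))
  b <- train(cfg, m, images = ns$rads_by_id(ph))
  expect_identical(a$loss_history, b$loss_history)
  expect_identical(a$disc$params, b$disc$params)
  expect_identical(a$gen$params, b$gen$params)
})

test_that("checkpoint resume reproduces the uninterrupted trajectory", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  ph <- tiny_set(6)
  m <- ns$rads_to_manifest(ph)
  cfg_full <- tiny_train_config("supervised", epochs = 4L,
                                checkpoint_every = 2L, out_dir = dir_a)
  full <- train(cfg_full, m, images = ns$rads_by_id(ph))
  cfg_half <- cfg_full  # identical schedule, interrupted after epoch 2
  cfg_half$epochs <- 2L
  cfg_half$out_dir <- dir_b
  train(cfg_half, m, images = ns$rads_by_id(ph))
  resumed <- train(cfg_full, m, images = ns$rads_by_id(ph),
                   resume = file.path(dir_b, "checkpoint_002.rds"))
  expect_equal(resumed$loss_history$L_l, full$loss_history$L_l)
  expect_identical(resumed$disc$params, full$disc$params)
  # checkpoints are self-describing
  ck <- load_checkpoint(file.path(dir_a, "checkpoint_004.rds"))
  expect_true(!is.null(ck$spec_json))
  expect_match(as.character(ck$spec_json), "small-cnn")
})

test_that("experiment wrappers produce the reporting layout", {
  ph <- tiny_set(10)
  cfg <- tiny_train_config("semi_supervised", epochs = 1L)
  rep1 <- run_semisup_experiment(cfg, ph, fractions = 0.5, k_folds = 2L,
                                 modes = "semi_supervised")
  expect_equal(nrow(rep1), 2)  # one row per fold
  expect_true(all(c("fraction", "mode", "fold", "dice", "jaccard") %in%
                    names(rep1)))
  expect_true(all(rep1$dice >= 0 & rep1$dice <= 1))
  rep2 <- run_semisup_experiment(cfg, ph, fractions = 0.5, k_folds = 1L,
                                 modes = c("semi_supervised", "supervised"))
  expect_equal(nrow(rep2), 2)  # one row per mode on the shared holdout
  expect_error(run_semisup_experiment(cfg, ph, fractions = 1.5, k_folds = 2L),
               class = "usgan_validation_error")

  src <- tiny_set(10, seed = 4)
  tgt <- shift_domain(tiny_set(10, seed = 5), domain_shift(gamma = 1.5),
                      seed = 9)
  rep3 <- run_uda_experiment(tiny_train_config("uda", epochs = 1L), src, tgt)
  expect_setequal(rep3$arm, c("sup_source", "t_noda", "uda_target", "s_test"))
  expect_true(all(is.finite(rep3$dice)))
})
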