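test_that("parameter counting matches closed forms for single layers", {
  pw <- list(params = list(W = array(0, c(1, 1, 8, 4)), b = numeric(4)))
  expect_equal(count_parameters(pw), 8 * 4 + 4)          # 36
  k4 <- list(params = list(W = array(0, c(4, 4, 8, 4)), b = numeric(4)))
  expect_equal(count_parameters(k4), 4 * 4 * 8 * 4 + 4)  # 516
  expect_equal(count_parameters(list(params = list())), 0)
})

test_that("the full-scale generator reproduces the published parameter budget", {
  set.seed(50)
  reduced <- build_generator(generator_spec(1024L))
  n_red <- count_parameters(reduced)
  expect_equal(signif(n_red, 3), 1.35e7)
  full <- build_generator(generator_spec(1024L, pointwise_reduction = FALSE))
  n_full <- count_parameters(full)
  expect_equal(signif(n_full, 3), 1.34e8)
  expect_gte(n_full / n_red, 5)
})

test_that("FLOP accounting follows the documented convention", {
  # 1x1 convolution, 1 -> 1 channel, on a 2x2 input: 8 MAC-ops + 4 bias adds
  toy <- structure(list(arch = list(list(kind = "conv", k = 1L, cin = 1L,
                                         cout = 1L, res = 1)),
                        spec = list(input_resolution = 2L)),
                   class = "usgan_discriminator")
  expect_equal(count_flops(toy), 2 * 2 * 1 * 2 + 4)
  expect_equal(count_flops(list(arch = list())), 0)
  # doubling the input resolution quadruples every convolution's count
  set.seed(51)
  d <- build_discriminator(tiny_disc_spec(32L))
  expect_equal(count_flops(d, 64L), 4 * count_flops(d, 32L))
})

test_that("the generator maps noise to unit-interval images deterministically", {
  set.seed(52)
  gen <- build_generator(tiny_gen_spec(64L))
  z <- sample_noise(3, 100)
  out <- generate_images(gen, z)
  expect_equal(dim(out), c(64, 64, 1, 3))
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  expect_identical(out, generate_images(gen, z))
  expect_error(generate_images(gen, matrix(0, 2, 64)),
               class = "usgan_validation_error")
  expect_error(generator_spec(64L, channel_schedule = c(8L, 4L, 4L, 4L)),
               class = "usgan_validation_error")
})

test_that("discriminator output is an input-sized per-pixel distribution", {
  set.seed(53)
  ns <- asNamespace("usgan")
  for (res in c(32L, 64L)) {
    d <- build_discriminator(tiny_disc_spec(res))
    x <- array(runif(res * res * 2), c(res, res, 1L, 2L))
    f <- ns$discriminator_forward(d, x)
    expect_equal(dim(f$probs), c(res, res, 3L, 2L))
    expect_lt(max(abs(apply(f$probs, c(1, 2, 4), sum) - 1)), 1e-5)
    expect_gte(min(f$probs), 0)
  }
  # degenerate all-zero input still yields finite probabilities
  d <- build_discriminator(tiny_disc_spec(32L))
  z <- array(0, c(32, 32, 1, 1))
  f <- ns$discriminator_forward(d, z)
  expect_true(all(is.finite(f$probs)))
  expect_error(ns$discriminator_forward(d, array(0, c(16, 16, 1, 1))),
               class = "usgan_validation_error")
  expect_error(discriminator_spec("small-cnn", input_resolution = 50L),
               class = "usgan_validation_error")
})

test_that("skip connections add parameters but preserve the output contract", {
  set.seed(54)
  on <- build_discriminator(tiny_disc_spec(32L, skip = TRUE))
  off <- build_discriminator(tiny_disc_spec(32L, skip = FALSE))
  expect_gt(count_parameters(on), count_parameters(off))
  ns <- asNamespace("usgan")
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_equal(dim(ns$discriminator_forward(off, x)$probs), c(32, 32, 3, 1))
})

test_that("a randomly initialised ResNet-50 encoder drives the same decoder", {
  set.seed(55)
  spec <- discriminator_spec("resnet50", 64L,
                             decoder_channel_schedule = c(32L, 16L, 8L, 8L))
  d <- build_discriminator(spec)
  expect_gt(count_parameters(d), 2e7)  # bottleneck stacks dominate
  ns <- asNamespace("usgan")
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  f <- ns$discriminator_forward(d, x)
  expect_equal(dim(f$probs), c(64, 64, 3, 1))
  expect_lt(max(abs(apply(f$probs, c(1, 2, 4), sum) - 1)), 1e-5)
  expect_error(discriminator_spec("resnet50", 48L),
               class = "usgan_validation_error")
})

test_that("checkpoint weights reload into an identical model", {
  dir <- withr::local_tempdir()
  set.seed(56)
  d <- build_discriminator(tiny_disc_spec(32L))
  p <- file.path(dir, "w.rds")
  saveRDS(list(params = d$params), p)
  d2 <- build_discriminator(tiny_disc_spec(32L), weights = p)
  ns <- asNamespace("usgan")
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(ns$discriminator_forward(d, x)$probs,
                   ns$discriminator_forward(d2, x)$probs)
})
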