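# Finite-difference verification of the layer primitives and of complete
# networks. These pin down the backward passes that the adversarial training
# relies on.

numgrad <- function(fwd, get, set, gy, eps = 1e-6) {
  v <- get()
  g <- v * 0
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- v[i] + eps; set(vp); fp <- sum(fwd() * gy)
    vm <- v; vm[i] <- v[i] - eps; set(vm); fm <- sum(fwd() * gy)
    set(v)
    g[i] <- (fp - fm) / (2 * eps)
  }
  g
}

test_that("convolution gradients match finite differences", {
  set.seed(61)
  ns <- asNamespace("usgan")
  env <- new.env()
  env$x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  env$W <- array(rnorm(3 * 3 * 2 * 3) * 0.5, c(3, 3, 2, 3))
  env$b <- rnorm(3)
  f <- ns$conv_fwd(env$x, env$W, env$b, 2L, 1L)
  gy <- array(rnorm(length(f$out)), dim(f$out))
  bw <- ns$conv_bwd(f$cache, gy)
  fwd <- function() ns$conv_fwd(env$x, env$W, env$b, 2L, 1L)$out
  expect_equal(bw$gw, numgrad(fwd, function() env$W,
                              function(v) env$W <- v, gy), tolerance = 1e-6)
  expect_equal(bw$gx, numgrad(fwd, function() env$x,
                              function(v) env$x <- v, gy), tolerance = 1e-6)
  expect_equal(bw$gb, numgrad(fwd, function() env$b,
                              function(v) env$b <- v, gy), tolerance = 1e-6)
})

test_that("transposed convolution gradients match finite differences", {
  set.seed(62)
  ns <- asNamespace("usgan")
  env <- new.env()
  env$x <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  env$W <- array(rnorm(4 * 4 * 2 * 3) * 0.5, c(4, 4, 2, 3))
  env$b <- rnorm(2)
  f <- ns$tconv_fwd(env$x, env$W, env$b)
  expect_equal(dim(f$out), c(6, 6, 2, 2))  # stride-2 upsampling
  gy <- array(rnorm(length(f$out)), dim(f$out))
  bw <- ns$tconv_bwd(f$cache, gy)
  fwd <- function() ns$tconv_fwd(env$x, env$W, env$b)$out
  expect_equal(bw$gw, numgrad(fwd, function() env$W,
                              function(v) env$W <- v, gy), tolerance = 1e-6)
  expect_equal(bw$gx, numgrad(fwd, function() env$x,
                              function(v) env$x <- v, gy), tolerance = 1e-6)
  expect_equal(bw$gb, numgrad(fwd, function() env$b,
                              function(v) env$b <- v, gy), tolerance = 1e-6)
})

test_that("instance norm and pooling gradients match finite differences", {
  set.seed(63)
  ns <- asNamespace("usgan")
  env <- new.env()
  env$x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  env$g <- runif(3, 0.5, 1.5)
  env$b <- rnorm(3)
  f <- ns$instnorm_fwd(env$x, env$g, env$b)
  gy <- array(rnorm(length(f$out)), dim(f$out))
  bw <- ns$instnorm_bwd(f$cache, gy)
  fwd <- function() ns$instnorm_fwd(env$x, env$g, env$b)$out
  expect_equal(bw$gx, numgrad(fwd, function() env$x,
                              function(v) env$x <- v, gy), tolerance = 1e-5)
  expect_equal(bw$gg, numgrad(fwd, function() env$g,
                              function(v) env$g <- v, gy), tolerance = 1e-6)
  expect_equal(bw$gb, numgrad(fwd, function() env$b,
                              function(v) env$b <- v, gy), tolerance = 1e-6)

  env$x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  fm <- ns$maxpool_fwd(env$x, 3L, 2L, 1L)
  gy <- array(rnorm(length(fm$out)), dim(fm$out))
  gx <- ns$maxpool_bwd(fm$cache, gy)
  fwd <- function() ns$maxpool_fwd(env$x, 3L, 2L, 1L)$out
  expect_equal(gx, numgrad(fwd, function() env$x,
                           function(v) env$x <- v, gy), tolerance = 1e-5)
})

test_that("whole-network gradients agree with finite differences", {
  set.seed(64)
  ns <- asNamespace("usgan")
  disc <- build_discriminator(tiny_disc_spec(32L))
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  masks <- random_mask(32, 32, 2)
  f <- ns$discriminator_forward(disc, x, train = TRUE)
  bw <- ns$discriminator_backward(disc, f$cache,
                                  ns$grad_supervised(f$probs, masks),
                                  want_gx = TRUE)
  loss_of <- function(d) supervised_loss(ns$discriminator_forward(d, x)$probs,
                                         masks)
  for (nm in sample(names(disc$params), 6)) {
    i <- sample(length(disc$params[[nm]]), 1)
    eps <- 1e-5
    dp <- disc; dp$params[[nm]][i] <- dp$params[[nm]][i] + eps
    dm <- disc; dm$params[[nm]][i] <- dm$params[[nm]][i] - eps
    num <- (loss_of(dp) - loss_of(dm)) / (2 * eps)
    expect_equal(bw$grads[[nm]][i], num, tolerance = 5e-3)
  }
  # gradient with respect to the input image (the generator pathway)
  i <- 500; eps <- 1e-5
  xp <- x; xp[i] <- x[i] + eps
  xm <- x; xm[i] <- x[i] - eps
  num <- (supervised_loss(ns$discriminator_forward(disc, xp)$probs, masks) -
          supervised_loss(ns$discriminator_forward(disc, xm)$probs, masks)) /
    (2 * eps)
  expect_equal(bw$gx[i], num, tolerance = 1e-4)

  gen <- build_generator(tiny_gen_spec(64L))
  z <- matrix(rnorm(2 * 100), 2)
  gf <- ns$generator_forward(gen, z, train = TRUE)
  gy <- array(rnorm(length(gf$out)), dim(gf$out))
  gg <- ns$generator_backward(gen, gf$cache, gy)
  sfun <- function(g) sum(ns$generator_forward(g, z)$out * gy)
  for (nm in sample(names(gen$params), 4)) {
    i <- sample(length(gen$params[[nm]]), 1)
    eps <- 1e-6
    gp <- gen; gp$params[[nm]][i] <- gp$params[[nm]][i] + eps
    gm <- gen; gm$params[[nm]][i] <- gm$params[[nm]][i] - eps
    num <- (sfun(gp) - sfun(gm)) / (2 * eps)
    expect_equal(gg[[nm]][i], num, tolerance = 1e-3)
  }
})
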