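test_that("closed-form loss values are reproduced on uniform maps", {
  u <- array(1 / 3, c(4, 4, 3, 2))
  m <- random_mask(4, 4, 2)
  expect_equal(supervised_loss(u, m), -log(1 / 3), tolerance = 1e-12)
  expect_equal(unsupervised_real_loss(u), -log(2 / 3), tolerance = 1e-12)
  expect_equal(fake_loss(u), -log(1 / 3), tolerance = 1e-12)
  expect_equal(generator_loss(u), log(1 / 3), tolerance = 1e-12)
  b <- discriminator_loss(annotated = list(probs = u, masks = m),
                          unannotated = u, generated = u)
  expect_equal(b$L_D, -log(1 / 3) - log(2 / 3) - log(1 / 3), tolerance = 1e-12)
})

test_that("perfect predictions give zero loss", {
  m <- random_mask(6, 6)
  p <- array(0, c(6, 6, 3, 1))
  p[, , 1, 1] <- m
  p[, , 2, 1] <- 1 - m
  expect_equal(supervised_loss(p, m), 0)
  expect_equal(unsupervised_real_loss(p), 0)
  pf <- array(0, c(6, 6, 3, 1)); pf[, , 3, ] <- 1
  expect_equal(fake_loss(pf), 0)
})

test_that("losses match the per-pixel double-loop oracle on random batches", {
  set.seed(31)
  for (trial in 1:10) {
    probs <- random_probs(8, 8, 3)
    masks <- random_mask(8, 8, 3)
    expect_equal(supervised_loss(probs, masks), oracle_supervised(probs, masks),
                 tolerance = 1e-6)
    expect_equal(unsupervised_real_loss(probs), oracle_unsup(probs),
                 tolerance = 1e-6)
    expect_equal(fake_loss(probs), oracle_fake(probs), tolerance = 1e-6)
    expect_equal(generator_loss(probs), oracle_gen(probs), tolerance = 1e-6)
  }
})

test_that("the discriminator loss decomposes into its three terms", {
  set.seed(32)
  pa <- random_probs(8, 8, 2); ma <- random_mask(8, 8, 2)
  pu <- random_probs(8, 8, 2); pg <- random_probs(8, 8, 2)
  b <- discriminator_loss(list(probs = pa, masks = ma), pu, pg)
  expect_equal(b$L_D, b$L_l + b$L_u + b$L_g, tolerance = 1e-6)
  expect_equal(b$L_l, supervised_loss(pa, ma))
  expect_equal(b$L_u, unsupervised_real_loss(pu))
  expect_equal(b$L_g, fake_loss(pg))
  expect_equal(unname(b$pixel_counts), c(128L, 128L, 128L))
  only_ann <- discriminator_loss(annotated = list(probs = pa, masks = ma))
  expect_equal(only_ann$L_D, only_ann$L_l)
  expect_equal(only_ann$L_u, 0)
  expect_error(discriminator_loss(), class = "usgan_validation_error")
})

test_that("generator loss is the negative of the fake loss", {
  set.seed(33)
  p <- random_probs(8, 8, 2)
  expect_equal(generator_loss(p), -fake_loss(p), tolerance = 1e-12)
})

test_that("losses stay finite on one-hot probability maps", {
  for (hot in 1:3) {
    p <- array(0, c(4, 4, 3, 2)); p[, , hot, ] <- 1
    m <- random_mask(4, 4, 2)
    vals <- c(supervised_loss(p, m), unsupervised_real_loss(p),
              fake_loss(p), generator_loss(p))
    expect_true(all(is.finite(vals)))
  }
})

test_that("analytic logit gradients match finite differences through softmax", {
  set.seed(34)
  logits <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  masks <- random_mask(4, 4, 2)
  ns <- asNamespace("usgan")
  cases <- list(
    list(fn = function(p) supervised_loss(p, masks),
         gr = function(p) ns$grad_supervised(p, masks)),
    list(fn = unsupervised_real_loss, gr = ns$grad_unsupervised_real),
    list(fn = fake_loss, gr = ns$grad_fake),
    list(fn = generator_loss, gr = function(p) ns$grad_generator(p)),
    list(fn = function(p) generator_loss(p, nonsaturating = TRUE),
         gr = function(p) ns$grad_generator(p, nonsaturating = TRUE)))
  for (cs in cases) {
    probs <- ns$softmax_channels(logits)
    ana <- cs$gr(probs)
    for (i in sample(length(logits), 5)) {
      eps <- 1e-6
      lp <- logits; lp[i] <- lp[i] + eps
      lm <- logits; lm[i] <- lm[i] - eps
      num <- (cs$fn(ns$softmax_channels(lp)) -
                cs$fn(ns$softmax_channels(lm))) / (2 * eps)
      expect_equal(ana[i], num, tolerance = 1e-5)
    }
  }
})

test_that("minimising the supervised loss alone recovers class frequencies", {
  # shared logits over pixels whose labels are 60% lung / 40% background:
  # the cross-entropy minimum is the empirical frequency vector
  set.seed(35)
  masks <- array(rep(c(1, 1, 1, 0, 0), 5), c(5, 5, 1))
  ns <- asNamespace("usgan")
  logits <- array(0, c(5, 5, 3, 1))
  shared <- c(0, 0, 0)
  for (step in 1:600) {
    for (k in 1:3) logits[, , k, ] <- shared[k]
    probs <- ns$softmax_channels(logits)
    g <- ns$grad_supervised(probs, masks)
    shared <- shared - 0.5 * apply(g, 3, sum)
  }
  for (k in 1:3) logits[, , k, ] <- shared[k]
  probs <- ns$softmax_channels(logits)
  expect_equal(probs[1, 1, 1, 1], 0.6, tolerance = 0.01)
  expect_equal(probs[1, 1, 2, 1], 0.4, tolerance = 0.01)
  expect_lt(probs[1, 1, 3, 1], 0.01)
})

test_that("image-level adversarial loss reproduces its closed forms", {
  expect_equal(original_gan_loss(c(1, 1, 1e-12), c(1, 1, 0)), 0,
               tolerance = 1e-6)
  expect_equal(original_gan_loss(rep(0.5, 4), c(1, 0, 1, 0)), log(2),
               tolerance = 1e-12)
  expect_error(original_gan_loss(0.5, c(1, 0)),
               class = "usgan_validation_error")
})

test_that("a gradient step on the generator loss lowers the fake probability", {
  set.seed(36)
  gen <- build_generator(tiny_gen_spec(64L))
  disc <- build_discriminator(tiny_disc_spec(64L))
  ns <- asNamespace("usgan")
  z <- matrix(rnorm(2 * 100), 2)
  gf <- ns$generator_forward(gen, z, train = TRUE)
  fg <- ns$discriminator_forward(disc, gf$out, train = TRUE)
  p0 <- mean(fg$probs[, , 3, ])
  bw <- ns$discriminator_backward(disc, fg$cache, ns$grad_generator(fg$probs),
                                  want_gx = TRUE)
  gg <- ns$generator_backward(gen, gf$cache, bw$gx)
  for (nm in names(gg)) gen$params[[nm]] <- gen$params[[nm]] - 1e-3 * gg[[nm]]
  p1 <- mean(ns$discriminator_forward(disc,
    ns$generator_forward(gen, z)$out)$probs[, , 3, ])
  expect_lt(p1, p0)
})
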