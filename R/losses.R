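# Pixel-level adversarial losses. A ClassProbMap batch is an array of dim
# (H, W, 3, N) (a single map (H, W, 3) is promoted), channel order
# (lung, background, fake). All expectations are realised as flat arithmetic
# means over every pixel in the batch. The logarithm is clamped below at
# 1e-8 so one-hot maps stay finite.

LUNG <- 1L; BACKGROUND <- 2L; FAKE <- 3L

safe_log <- function(p) log(pmax(p, 1e-8))

as_prob_batch <- function(probs, n_classes = 3L) {
  d <- dim(probs)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop_validation("probability map must be (H, W, %d) or (H, W, %d, N)",
                    n_classes, n_classes)
  if (length(d) == 3L) dim(probs) <- c(d, 1L)
  if (dim(probs)[3] != n_classes)
    stop_validation("probability map has %d channels, expected %d",
                    dim(probs)[3], n_classes)
  probs
}

as_mask_batch <- function(masks) {
  d <- dim(masks)
  if (is.null(d)) stop_validation("mask must be a matrix or array")
  if (length(d) == 2L) dim(masks) <- c(d, 1L)
  if (!all(masks %in% c(0, 1)))
    stop_validation("mask values must be exactly 0 or 1")
  masks
}

#' Supervised pixel loss on annotated images
#'
#' Mean over all annotated pixels of the negative log-probability that the
#' discriminator assigns to the true class: the lung channel where the mask
#' is 1 and the background channel where it is 0. This is the annotated-data
#' term of the discriminator objective.
#'
#' @param probs a ClassProbMap batch: array `(H, W, 3, N)` (or a single
#'   `(H, W, 3)` map), channels ordered (lung, background, fake).
#' @param masks binary masks `(H, W, N)` (or `(H, W)`) matching `probs`.
#' @return nonnegative scalar.
#' @export
supervised_loss <- function(probs, masks) {
  probs <- as_prob_batch(probs)
  masks <- as_mask_batch(masks)
  d <- dim(probs)
  if (!all(dim(masks) == d[c(1, 2, 4)]))
    stop_validation("mask shape (%s) does not match probability map (%s)",
                    paste(dim(masks), collapse = "x"),
                    paste(d[c(1, 2, 4)], collapse = "x"))
  p_true <- as.vector(probs[, , BACKGROUND, , drop = FALSE])
  m <- as.vector(masks) == 1
  p_true[m] <- as.vector(probs[, , LUNG, , drop = FALSE])[m]
  -mean(safe_log(p_true))
}

#' Unsupervised pixel loss on real, unannotated images
#'
#' Mean over pixels of `-log(1 - p_fake)`. There is no dedicated "real"
#' output channel: a pixel counts as real through the complement of its fake
#' probability, i.e. the summed lung and background probabilities.
#'
#' @inheritParams supervised_loss
#' @return nonnegative scalar.
#' @export
unsupervised_real_loss <- function(probs) {
  probs <- as_prob_batch(probs)
  -mean(safe_log(1 - as.vector(probs[, , FAKE, , drop = FALSE])))
}

#' Fake pixel loss on generated images
#'
#' Mean over pixels of `-log p_fake` for discriminator outputs on generated
#' images: the discriminator is trained to label every generated pixel fake.
#'
#' @inheritParams supervised_loss
#' @return nonnegative scalar.
#' @export
fake_loss <- function(probs) {
  probs <- as_prob_batch(probs)
  -mean(safe_log(as.vector(probs[, , FAKE, , drop = FALSE])))
}

#' Full discriminator loss
#'
#' Sums the three discriminator terms — supervised (annotated), unsupervised
#' real (unannotated), and fake (generated) — without weighting. Any input
#' may be `NULL` and then contributes zero, which realises the pure
#' supervised and the domain-adaptation configurations.
#'
#' @param annotated `NULL` or `list(probs = , masks = )` for annotated
#'   images.
#' @param unannotated `NULL` or a ClassProbMap batch for unannotated images.
#' @param generated `NULL` or a ClassProbMap batch for generated images.
#' @return an object of class `usgan_loss_bundle`: list with elements `L_l`,
#'   `L_u`, `L_g`, `L_D` and `pixel_counts`.
#' @export
discriminator_loss <- function(annotated = NULL, unannotated = NULL,
                               generated = NULL) {
  if (is.null(annotated) && is.null(unannotated) && is.null(generated))
    stop_validation("at least one of annotated, unannotated, generated required")
  n_px <- function(p) if (is.null(p)) 0L else prod(dim(as_prob_batch(p))[c(1, 2, 4)])
  L_l <- if (is.null(annotated)) 0 else
    supervised_loss(annotated$probs, annotated$masks)
  L_u <- if (is.null(unannotated)) 0 else unsupervised_real_loss(unannotated)
  L_g <- if (is.null(generated)) 0 else fake_loss(generated)
  structure(list(L_l = L_l, L_u = L_u, L_g = L_g, L_D = L_l + L_u + L_g,
                 pixel_counts = c(
                   n_annotated = if (is.null(annotated)) 0L else n_px(annotated$probs),
                   n_unannotated = n_px(unannotated),
                   n_generated = n_px(generated))),
            class = "usgan_loss_bundle")
}

#' Generator loss
#'
#' Mean over pixels of `+log p_fake` on discriminator outputs for generated
#' images. Minimising it drives the fake probability of generated pixels
#' down, i.e. pushes generated images toward the real data distribution.
#' The saturating form is the definition; `nonsaturating = TRUE` switches to
#' the common `-log(1 - p_fake)` surrogate with the same fixed points.
#'
#' @inheritParams supervised_loss
#' @param nonsaturating use the non-saturating surrogate.
#' @return scalar (can be negative).
#' @export
generator_loss <- function(probs, nonsaturating = FALSE) {
  probs <- as_prob_batch(probs)
  pf <- as.vector(probs[, , FAKE, , drop = FALSE])
  if (nonsaturating) -mean(safe_log(1 - pf)) else mean(safe_log(pf))
}

#' Image-level adversarial loss (original GAN ablation)
#'
#' Binary cross-entropy on image-level real probabilities, used by the
#' ablation arm in which a classification head discriminates whole real
#' images from generated ones while the decoder performs plain two-class
#' segmentation.
#'
#' @param p_real numeric vector of image-level probabilities of being real.
#' @param is_real logical (or 0/1) vector: which images are real.
#' @return nonnegative scalar.
#' @export
original_gan_loss <- function(p_real, is_real) {
  if (length(p_real) != length(is_real))
    stop_validation("p_real and is_real lengths differ")
  is_real <- as.numeric(is_real)
  -mean(is_real * safe_log(p_real) + (1 - is_real) * safe_log(1 - p_real))
}

# ---- gradients with respect to pre-softmax logits (training path) ----
# Each returns dLoss/dlogits for probs = softmax(logits), normalised by the
# same pixel count as the loss itself. Correctness is pinned down by
# finite-difference tests against the public loss functions.

grad_supervised <- function(probs, masks) {
  d <- dim(probs)
  npix <- prod(d[c(1, 2, 4)])
  onehot <- array(0, d)
  m <- as.vector(masks) == 1
  lung <- array(FALSE, d); lung[, , LUNG, ] <- m
  back <- array(FALSE, d); back[, , BACKGROUND, ] <- !m
  onehot[lung] <- 1; onehot[back] <- 1
  (probs - onehot) / npix
}

grad_unsupervised_real <- function(probs) {
  d <- dim(probs)
  npix <- prod(d[c(1, 2, 4)])
  q <- 1 - probs[, , FAKE, , drop = FALSE]  # total real probability
  g <- array(0, d)
  scale <- 1 / pmax(q, 1e-8)
  g[, , LUNG, ] <- probs[, , LUNG, ] * (1 - as.vector(scale))
  g[, , BACKGROUND, ] <- probs[, , BACKGROUND, ] * (1 - as.vector(scale))
  g[, , FAKE, ] <- probs[, , FAKE, ]
  g / npix
}

grad_fake <- function(probs) {
  d <- dim(probs)
  npix <- prod(d[c(1, 2, 4)])
  onehot <- array(0, d)
  onehot[, , FAKE, ] <- 1
  (probs - onehot) / npix
}

grad_generator <- function(probs, nonsaturating = FALSE) {
  # the non-saturating surrogate -log(1 - p_fake) shares its gradient form
  # with the unsupervised real loss
  if (nonsaturating) grad_unsupervised_real(probs) else -grad_fake(probs)
}

# two-class segmentation cross-entropy (original-approach decoder)
grad_supervised_2class <- function(probs, masks) {
  d <- dim(probs)
  npix <- prod(d[c(1, 2, 4)])
  onehot <- array(0, d)
  m <- as.vector(masks) == 1
  lung <- array(FALSE, d); lung[, , 1L, ] <- m
  back <- array(FALSE, d); back[, , 2L, ] <- !m
  onehot[lung] <- 1; onehot[back] <- 1
  (probs - onehot) / npix
}

supervised_loss_2class <- function(probs, masks) {
  p_true <- ifelse(as.vector(masks) == 1,
                   as.vector(probs[, , 1L, , drop = FALSE]),
                   as.vector(probs[, , 2L, , drop = FALSE]))
  -mean(safe_log(p_true))
}

# d/dlogit of BCE on sigmoid image-level head
grad_cls_bce <- function(p_real, is_real) {
  (p_real - as.numeric(is_real)) / length(p_real)
}
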