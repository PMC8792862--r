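#' Jaccard index (IoU) between two binary masks
#'
#' `|A intersect B| / |A union B|` over foreground pixels. When both masks
#' are empty the index is defined as 1 (perfect agreement on "no lung").
#'
#' @param pred,truth 0/1 matrices of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop_validation("mask shapes differ: %s vs %s",
                    paste(dim(pred), collapse = "x"),
                    paste(dim(truth), collapse = "x"))
  a <- pred == 1; b <- truth == 1
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Dice score between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; both empty gives 1. Related to the
#' Jaccard index by `D = 2 J / (1 + J)`.
#'
#' @inheritParams jaccard
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop_validation("mask shapes differ: %s vs %s",
                    paste(dim(pred), collapse = "x"),
                    paste(dim(truth), collapse = "x"))
  a <- pred == 1; b <- truth == 1
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Per-pixel class probabilities for an image
#'
#' Runs the discriminator and returns the per-pixel probability map over
#' (lung, background, fake).
#'
#' @param disc a `usgan_discriminator`.
#' @param rad a [radiograph()] or a numeric matrix in `[0, 1]`.
#' @return array `(H, W, 3)` whose pixel rows sum to 1.
#' @export
predict_probs <- function(disc, rad) {
  px <- if (inherits(rad, "usgan_radiograph")) rad$pixels else rad
  x <- array(px, c(nrow(px), ncol(px), 1L, 1L))
  p <- discriminator_forward(disc, x, train = FALSE)$probs
  array(p, dim(p)[1:3])
}

#' Predict a binary lung mask
#'
#' Per pixel, the two real classes are compared and the fake channel — a
#' training device, not a semantic label — is ignored: a pixel is lung iff
#' its lung probability strictly exceeds its background probability (ties go
#' to background).
#'
#' @param disc a trained `usgan_discriminator`.
#' @param rad a [radiograph()] or numeric matrix.
#' @return 0/1 integer matrix.
#' @export
predict_mask <- function(disc, rad) {
  probs <- predict_probs(disc, rad)
  pl <- probs[, , LUNG]
  pb <- if (dim(probs)[3] >= 2L) probs[, , BACKGROUND] else 1 - pl
  matrix(as.integer(pl > pb), nrow(pl), ncol(pl))
}

#' Evaluate a model over a manifest
#'
#' Predicts a mask for every entry with a ground-truth mask and reports
#' per-image Dice and Jaccard plus their mean and standard deviation
#' (metrics are computed per image, then averaged). Entries without masks
#' are skipped with a warning.
#'
#' @param disc a trained `usgan_discriminator`.
#' @param manifest a manifest data.frame.
#' @param images optional named list of in-memory [radiograph()]s keyed by
#'   the manifest image column.
#' @param out_csv optional path; per-image results are written as CSV.
#' @return data.frame with columns image_id, dice, jaccard; the summary is
#'   attached as attributes `mean_dice`, `sd_dice`, `mean_jaccard`,
#'   `sd_jaccard`.
#' @export
evaluate_manifest <- function(disc, manifest, images = NULL, out_csv = NULL) {
  validate_manifest(manifest)
  res <- disc$spec$input_resolution
  has_mask <- !is.na(manifest$mask) & nzchar(as.character(manifest$mask))
  in_mem <- !is.null(images) & manifest$image %in% names(images)
  usable <- has_mask | in_mem
  if (any(!usable)) {
    warning(sprintf("skipping %d entries without ground-truth masks: %s",
                    sum(!usable),
                    paste(head(manifest$image[!usable], 5), collapse = ", ")))
    manifest <- manifest[usable, , drop = FALSE]
  }
  rads <- load_entries(manifest, res, images = images, with_masks = TRUE)
  no_mask <- vapply(rads, function(r) is.null(r$mask), TRUE)
  if (any(no_mask)) {
    warning(sprintf("skipping %d entries without ground-truth masks: %s",
                    sum(no_mask),
                    paste(head(manifest$image[no_mask], 5), collapse = ", ")))
    rads <- rads[!no_mask]
  }
  rows <- lapply(rads, function(r) {
    pred <- predict_mask(disc, r)
    data.frame(image_id = r$image_id, dice = dice(pred, r$mask),
               jaccard = jaccard(pred, r$mask), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_dice") <- mean(out$dice)
  attr(out, "sd_dice") <- if (nrow(out) > 1) sd(out$dice) else 0
  attr(out, "mean_jaccard") <- mean(out$jaccard)
  attr(out, "sd_jaccard") <- if (nrow(out) > 1) sd(out$jaccard) else 0
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

# mean Dice / Jaccard of a model over a list of radiographs with masks
evaluate_rads <- function(disc, rads) {
  d <- vapply(rads, function(r) dice(predict_mask(disc, r), r$mask), 0)
  j <- vapply(rads, function(r) jaccard(predict_mask(disc, r), r$mask), 0)
  c(dice = mean(d), jaccard = mean(j),
    sd_dice = if (length(d) > 1) sd(d) else 0,
    sd_jaccard = if (length(j) > 1) sd(j) else 0)
}
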