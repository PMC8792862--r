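#' Radiograph container
#'
#' A lightweight container for one grayscale image with intensities in the
#' unit interval, an optional binary lung mask of identical shape, and an
#' optional domain tag.
#'
#' @param pixels numeric matrix, values in `[0, 1]`.
#' @param image_id character identifier.
#' @param mask optional 0/1 integer matrix of identical shape.
#' @param domain_tag optional string, e.g. `"source"` or `"target"`.
#' @return an object of class `usgan_radiograph`.
#' @export
radiograph <- function(pixels, image_id, mask = NULL, domain_tag = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop_validation("pixels must be a nonempty numeric matrix")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop_validation("pixel intensities must lie in [0, 1]")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(pixels)))
      stop_validation("mask shape (%s) differs from pixels (%s)",
                      paste(dim(mask), collapse = "x"),
                      paste(dim(pixels), collapse = "x"))
    if (!all(mask %in% c(0L, 1L)))
      stop_validation("mask values must be exactly 0 or 1")
    storage.mode(mask) <- "integer"
  }
  structure(list(image_id = as.character(image_id), pixels = pixels,
                 mask = mask, domain_tag = domain_tag),
            class = "usgan_radiograph")
}

#' @export
print.usgan_radiograph <- function(x, ...) {
  cat(sprintf("<radiograph %s: %dx%d, %s mask%s>\n", x$image_id,
              nrow(x$pixels), ncol(x$pixels),
              if (is.null(x$mask)) "no" else "with",
              if (is.null(x$domain_tag)) "" else paste0(", ", x$domain_tag)))
  invisible(x)
}

#' Phantom generator configuration
#'
#' Parameters of the synthetic chest-radiograph-like phantoms: two dark
#' elliptical lung fields (radiolucent, hence below the background level) on
#' a brighter background crossed by a horizontal sinusoidal rib texture,
#' plus i.i.d. Gaussian noise. Masks delimit the ellipse interiors exactly,
#' so evaluation metrics on phantoms have no annotation error.
#'
#' @param resolution side length in pixels (>= 32).
#' @param n_images number of phantoms.
#' @param lung_eccentricity_range range of the vertical/horizontal semi-axis
#'   ratio of each lung ellipse.
#' @param lung_area_fraction_range range of the total (both lungs) mask area
#'   as a fraction of the image.
#' @param rib_frequency rib cycles per image height.
#' @param rib_amplitude amplitude of the rib sinusoid, in `[0, 1)`.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param background_level,lung_level mean intensities of background and
#'   lung interior; `lung_level < background_level`.
#' @param seed RNG seed; generation is a pure function of config and seed.
#' @return an object of class `usgan_phantom_config`.
#' @export
phantom_config <- function(resolution = 64L, n_images = 200L,
                           lung_eccentricity_range = c(1.4, 2.2),
                           lung_area_fraction_range = c(0.15, 0.30),
                           rib_frequency = 6, rib_amplitude = 0.08,
                           noise_sd = 0.05, background_level = 0.75,
                           lung_level = 0.30, seed = 1L) {
  if (resolution < 32L) stop_validation("resolution must be >= 32")
  if (n_images < 1L) stop_validation("n_images must be >= 1")
  if (lung_level >= background_level)
    stop_validation("lung_level must be below background_level")
  if (rib_amplitude < 0 || rib_amplitude >= 1)
    stop_validation("rib_amplitude must be in [0, 1)")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  structure(list(resolution = as.integer(resolution),
                 n_images = as.integer(n_images),
                 lung_eccentricity_range = lung_eccentricity_range,
                 lung_area_fraction_range = lung_area_fraction_range,
                 rib_frequency = rib_frequency,
                 rib_amplitude = rib_amplitude,
                 noise_sd = noise_sd,
                 background_level = background_level,
                 lung_level = lung_level,
                 seed = as.integer(seed)),
            class = "usgan_phantom_config")
}

# rasterise one axis-aligned ellipse: TRUE inside
ellipse_mask <- function(res, cx, cy, a, b) {
  x <- matrix(seq_len(res), res, res)          # column (horizontal) index
  y <- matrix(seq_len(res), res, res, byrow = TRUE)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 < 1      # note: x horizontal, y vertical
}

#' Generate synthetic phantoms
#'
#' Draws `n_images` phantoms under the configuration. Each image contains
#' two non-overlapping ellipses (left and right lung fields) with randomised
#' centres and axes; the exact rasterised interiors form the ground-truth
#' mask. Fully reproducible from `config$seed`.
#'
#' @param config a [phantom_config()].
#' @param domain_tag optional tag stored on every phantom.
#' @return list of [radiograph()] objects with masks.
#' @export
generate_phantoms <- function(config, domain_tag = NULL) {
  stopifnot(inherits(config, "usgan_phantom_config"))
  res <- config$resolution
  with_seed(config$seed, {
    lapply(seq_len(config$n_images), function(i) {
      ok <- FALSE
      for (attempt in seq_len(100L)) {
        frac <- runif(1, config$lung_area_fraction_range[1],
                      config$lung_area_fraction_range[2])
        area_each <- frac * res^2 / 2            # pi * a * b per lung
        ecc <- runif(2, config$lung_eccentricity_range[1],
                     config$lung_eccentricity_range[2])
        a <- sqrt(area_each / (pi * ecc))        # horizontal semi-axis
        b <- a * ecc                             # vertical semi-axis
        cxl <- res * runif(1, 0.24, 0.32); cxr <- res * runif(1, 0.68, 0.76)
        cy <- res * runif(2, 0.45, 0.55)
        fits <- cxl - a[1] > 1 && cxr + a[2] < res &&
          all(cy - b > 1) && all(cy + b < res) &&
          cxl + a[1] < cxr - a[2]                # non-overlap along x
        if (fits) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf(paste0("phantom geometry infeasible after 100 attempts ",
                            "(resolution %d, area fraction %.2f-%.2f, ",
                            "eccentricity %.2f-%.2f)"),
                     res, config$lung_area_fraction_range[1],
                     config$lung_area_fraction_range[2],
                     config$lung_eccentricity_range[1],
                     config$lung_eccentricity_range[2]))
      m_left <- ellipse_mask(res, cxl, cy[1], a[1], b[1])
      m_right <- ellipse_mask(res, cxr, cy[2], a[2], b[2])
      mask <- m_left | m_right
      ellipses <- list(left = c(cx = cxl, cy = cy[1], a = a[1], b = b[1]),
                       right = c(cx = cxr, cy = cy[2], a = a[2], b = b[2]))
      y <- matrix(seq_len(res), res, res, byrow = TRUE)
      ribs <- config$rib_amplitude *
        sin(2 * pi * config$rib_frequency * y / res + runif(1, 0, 2 * pi))
      img <- matrix(config$background_level, res, res)
      img[mask] <- config$lung_level
      if (config$rib_amplitude > 0) img <- img + ribs
      if (config$noise_sd > 0)
        img <- img + matrix(rnorm(res^2, 0, config$noise_sd), res, res)
      img <- pmin(pmax(img, 0), 1)
      r <- radiograph(img, sprintf("phantom_%04d", i),
                      mask = matrix(as.integer(mask), res, res),
                      domain_tag = domain_tag)
      r$ellipses <- ellipses  # generating parameters, kept for verification
      r
    })
  })
}

#' Intensity domain shift
#'
#' Describes a purely intensity-based domain shift emulating acquisition
#' differences between imaging sites: a gamma curve, a contrast scale, a
#' smooth multiplicative-free additive bias field, and extra noise. The
#' identity shift maps any image to itself exactly.
#'
#' @param gamma exponent applied to intensities (> 0).
#' @param contrast_scale multiplicative contrast factor (> 0).
#' @param bias_field_amplitude peak amplitude of the smooth additive bias
#'   field, in `[0, 1)`.
#' @param bias_field_smoothness spatial scale of the bias field as a
#'   fraction of the image side; frequencies up to `1/smoothness` cycles per
#'   image are used.
#' @param noise_sd_delta standard deviation of additional Gaussian noise.
#' @return an object of class `usgan_domain_shift`.
#' @export
domain_shift <- function(gamma = 1, contrast_scale = 1,
                         bias_field_amplitude = 0,
                         bias_field_smoothness = 0.5,
                         noise_sd_delta = 0) {
  if (gamma <= 0) stop_validation("gamma must be > 0")
  if (contrast_scale <= 0) stop_validation("contrast_scale must be > 0")
  if (bias_field_amplitude < 0 || bias_field_amplitude >= 1)
    stop_validation("bias_field_amplitude must be in [0, 1)")
  if (bias_field_smoothness <= 0)
    stop_validation("bias_field_smoothness must be > 0")
  structure(list(gamma = gamma, contrast_scale = contrast_scale,
                 bias_field_amplitude = bias_field_amplitude,
                 bias_field_smoothness = bias_field_smoothness,
                 noise_sd_delta = noise_sd_delta),
            class = "usgan_domain_shift")
}

is_identity_shift <- function(shift) {
  shift$gamma == 1 && shift$contrast_scale == 1 &&
    shift$bias_field_amplitude == 0 && shift$noise_sd_delta == 0
}

# smooth random surface with max |s| = 1: a few random low-frequency cosines
random_bias_surface <- function(res, smoothness) {
  x <- matrix(seq_len(res) / res, res, res)
  y <- matrix(seq_len(res) / res, res, res, byrow = TRUE)
  s <- matrix(0, res, res)
  fmax <- 1 / smoothness
  for (k in 1:3) {
    f <- runif(1, 0.25 * fmax, fmax)
    th <- runif(1, 0, 2 * pi)
    ph <- runif(1, 0, 2 * pi)
    s <- s + cos(2 * pi * f * (cos(th) * x + sin(th) * y) + ph)
  }
  s / max(abs(s))
}

#' Apply an intensity domain shift to a radiograph
#'
#' Output intensities are
#' `clip(contrast_scale * pixels^gamma + bias_field + noise, 0, 1)`; the
#' mask, being a property of anatomy rather than acquisition, is carried
#' over unchanged. The identity shift returns the input bitwise.
#'
#' @param rad a [radiograph()].
#' @param shift a [domain_shift()].
#' @param seed RNG seed for the bias field and noise.
#' @param domain_tag optional new domain tag for the output.
#' @return a shifted [radiograph()].
#' @export
apply_domain_shift <- function(rad, shift, seed = 1L, domain_tag = rad$domain_tag) {
  stopifnot(inherits(rad, "usgan_radiograph"),
            inherits(shift, "usgan_domain_shift"))
  if (is_identity_shift(shift)) {
    out <- rad
    out$domain_tag <- domain_tag
    return(out)
  }
  res <- nrow(rad$pixels)
  with_seed(seed, {
    img <- shift$contrast_scale * rad$pixels^shift$gamma
    if (shift$bias_field_amplitude > 0) {
      img <- img + shift$bias_field_amplitude *
        random_bias_surface(res, shift$bias_field_smoothness)
    }
    if (shift$noise_sd_delta > 0) {
      img <- img + matrix(rnorm(length(img), 0, shift$noise_sd_delta),
                          nrow = res)
    }
    img <- pmin(pmax(img, 0), 1)
    radiograph(img, rad$image_id, mask = rad$mask, domain_tag = domain_tag)
  })
}

#' Shift a whole set of phantoms into a new domain
#'
#' @param rads list of [radiograph()] objects.
#' @param shift a [domain_shift()].
#' @param seed base seed; image `i` uses `seed + i` so fields differ between
#'   images but the whole operation is reproducible.
#' @param domain_tag tag stored on the shifted images.
#' @return list of shifted radiographs.
#' @export
shift_domain <- function(rads, shift, seed = 1L, domain_tag = "target") {
  lapply(seq_along(rads), function(i)
    apply_domain_shift(rads[[i]], shift, seed = seed + i,
                       domain_tag = domain_tag))
}
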