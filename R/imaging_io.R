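# Image, mask and manifest I/O plus the split protocols. Images are 8- or
# 16-bit grayscale PNG/TIFF; masks are 8-bit PNG with 0 = background and
# 255 = lung. A manifest is a data.frame with columns image, mask, pool,
# fold (and optionally split); an empty mask field means unannotated.

read_gray <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  }, error = function(e) {
    stop(sprintf("cannot decode image '%s': %s", path, conditionMessage(e)))
  })
  if (length(dim(img)) == 3L) {
    # collapse any colour/alpha planes to luminance over the first 3 channels
    nc <- min(dim(img)[3], 3L)
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  if (length(img) == 0L || any(dim(img) == 0L))
    stop(sprintf("image '%s' is zero-sized", path))
  img
}

resize_gray <- function(img, target, filter = c("bilinear", "none")) {
  filter <- match.arg(filter)
  if (nrow(img) == target && ncol(img) == target) return(img)
  out <- EBImage::resize(EBImage::Image(img), w = target, h = target,
                         filter = filter)
  matrix(EBImage::imageData(out), target, target)
}

#' Load a radiograph image
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF, rescales intensities to
#' `[0, 1]` by the dtype maximum, and resizes to the target resolution with
#' the requested interpolation (bilinear by default). Channel replication to
#' RGB happens at the network input, not here.
#'
#' @param path file path.
#' @param target_resolution output side length.
#' @param interpolation `"bilinear"` or `"none"` (nearest neighbour).
#' @param image_id identifier; defaults to the file name.
#' @return a [radiograph()] (without mask).
#' @export
load_radiograph <- function(path, target_resolution,
                            interpolation = c("bilinear", "none"),
                            image_id = tools::file_path_sans_ext(basename(path))) {
  interpolation <- match.arg(interpolation)
  img <- read_gray(path)
  img <- resize_gray(img, target_resolution, interpolation)
  img <- pmin(pmax(img, 0), 1)
  radiograph(img, image_id)
}

#' Load a binary mask
#'
#' Reads a mask image, thresholds it at half the source maximum (so both
#' 0/255 and 0/1 dialects decode to the same labels) and resizes with
#' nearest-neighbour interpolation only, so no fractional label values can
#' arise.
#'
#' @param path file path.
#' @param target_resolution output side length.
#' @return 0/1 integer matrix.
#' @export
load_mask <- function(path, target_resolution) {
  img <- read_gray(path)
  mx <- max(img)
  bin <- if (mx == 0) img * 0 else (img > mx / 2) * 1
  bin <- resize_gray(bin, target_resolution, "none")
  matrix(as.integer(bin > 0.5), target_resolution, target_resolution)
}

#' Write a radiograph to an 8-bit grayscale PNG
#' @param rad a [radiograph()].
#' @param path output file path.
#' @export
save_radiograph <- function(rad, path) {
  png::writePNG(rad$pixels, path)
  invisible(path)
}

#' Write a binary mask to an 8-bit PNG (0 = background, 255 = lung)
#' @param mask 0/1 integer matrix.
#' @param path output file path.
#' @export
save_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

valid_pools <- c("annotated", "unannotated", "source", "target")

validate_manifest <- function(manifest) {
  need <- c("image", "pool")
  if (!is.data.frame(manifest) || !all(need %in% names(manifest)))
    stop_validation("manifest must be a data.frame with columns image, pool")
  if (!all(manifest$pool %in% valid_pools))
    stop_validation("manifest pools must be one of: %s",
                    paste(valid_pools, collapse = ", "))
  has_mask <- !is.na(manifest$mask) & nzchar(as.character(manifest$mask))
  must <- manifest$pool %in% c("annotated", "source")
  if (any(must & !has_mask))
    stop_validation("every annotated/source entry needs a mask path")
  invisible(manifest)
}

#' Read a dataset manifest (CSV)
#'
#' @param path CSV with header `image,mask,pool,fold` (optionally `split`,
#'   `domain`); an empty mask field marks an unannotated image.
#' @return a manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if ("fold" %in% names(m)) m$fold <- suppressWarnings(as.integer(m$fold))
  m$mask[is.na(m$mask)] <- ""
  validate_manifest(m)
  m
}

#' Write a dataset manifest (CSV)
#' @param manifest a manifest data.frame.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Assign cross-validation folds and an annotated subset
#'
#' Assigns every entry a fold index (balanced, uniformly at random under
#' `seed`) and marks an annotated fraction of each fold. Because the subset
#' is stratified within folds, every training portion (the union of k-1
#' folds) contains exactly `ceiling(fraction * fold size)` annotated images
#' per fold it contains.
#'
#' @param manifest a manifest data.frame whose entries all carry masks.
#' @param annotated_fraction fraction in `(0, 1]` marked annotated.
#' @param k_folds number of folds (>= 2).
#' @param seed RNG seed; the assignment is a pure function of inputs + seed.
#' @return the manifest with `fold` filled and `pool` set to
#'   annotated/unannotated.
#' @export
make_semisup_splits <- function(manifest, annotated_fraction, k_folds, seed) {
  validate_manifest(manifest)
  n <- nrow(manifest)
  if (annotated_fraction <= 0 || annotated_fraction > 1)
    stop_validation("annotated_fraction must be in (0, 1]")
  if (k_folds < 2L) stop_validation("k_folds must be >= 2")
  if (n < k_folds) stop_validation("fewer entries (%d) than folds (%d)", n, k_folds)
  has_mask <- !is.na(manifest$mask) & nzchar(as.character(manifest$mask))
  if (!all(has_mask))
    stop_validation("all entries need masks to form an annotated subset")
  with_seed(seed, {
    fold <- sample(rep(seq_len(k_folds), length.out = n))
    pool <- rep("unannotated", n)
    for (f in seq_len(k_folds)) {
      idx <- which(fold == f)
      n_ann <- ceiling(annotated_fraction * length(idx))
      pool[sample(idx, n_ann)] <- "annotated"
    }
    manifest$fold <- fold
    manifest$pool <- pool
    manifest
  })
}

#' Split source and target domains for domain adaptation
#'
#' Splits each domain into train/validation/test portions (default 7:1:2)
#' reproducibly. The training pool couples annotated source images with
#' unannotated target images; target masks are retained in the manifest for
#' evaluation only and are never consumed during training.
#'
#' @param source manifest of the annotated source domain (all entries need
#'   masks).
#' @param target manifest of the unannotated target domain.
#' @param ratios length-3 positive vector summing to 1.
#' @param seed RNG seed.
#' @return a combined manifest with columns `pool` (source/target) and
#'   `split` (train/val/test).
#' @export
make_uda_splits <- function(source, target, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  validate_manifest(source); validate_manifest(target)
  if (nrow(source) == 0L || nrow(target) == 0L)
    stop_validation("source and target domains must be nonempty")
  if (length(ratios) != 3L || any(ratios <= 0))
    stop_validation("ratios must be 3 positive numbers")
  if (abs(sum(ratios) - 1) > 1e-9)
    stop_validation("ratios must sum to 1 (got %.10f)", sum(ratios))
  has_mask <- !is.na(source$mask) & nzchar(as.character(source$mask))
  if (!all(has_mask))
    stop_validation("all source entries need masks")
  split_one <- function(m, pool_name) {
    n <- nrow(m)
    counts <- diff(c(0L, round(cumsum(ratios) * n)))
    lab <- rep(c("train", "val", "test"), counts)
    m$split <- sample(lab)
    m$pool <- pool_name
    m
  }
  with_seed(seed, {
    s <- split_one(source, "source")
    t <- split_one(target, "target")
    rbind(s[intersect(names(s), names(t))], t[intersect(names(s), names(t))])
  })
}

#' Materialise phantoms as an image/mask directory plus manifest
#'
#' Writes each phantom image and mask as PNG files and returns (and
#' optionally writes) the corresponding manifest.
#'
#' @param rads list of [radiograph()] objects.
#' @param dir output directory (created if needed).
#' @param manifest_path optional CSV path for the manifest.
#' @return the manifest data.frame (invisibly if written).
#' @export
phantoms_to_manifest <- function(rads, dir, manifest_path = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(rads, function(r) {
    ip <- file.path(dir, "images", paste0(r$image_id, ".png"))
    save_radiograph(r, ip)
    mp <- ""
    if (!is.null(r$mask)) {
      mp <- file.path(dir, "masks", paste0(r$image_id, ".png"))
      save_mask(r$mask, mp)
    }
    data.frame(image = ip, mask = mp,
               pool = if (nzchar(mp)) "annotated" else "unannotated",
               fold = NA_integer_, stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, rows)
  if (!is.null(manifest_path)) {
    write_manifest(m, manifest_path)
    return(invisible(m))
  }
  m
}

# Resolve manifest rows to radiograph objects; `images` may supply in-memory
# radiographs keyed by the manifest's image column.
load_entries <- function(manifest, resolution, images = NULL, with_masks = TRUE) {
  lapply(seq_len(nrow(manifest)), function(i) {
    key <- manifest$image[i]
    if (!is.null(images) && !is.null(images[[key]])) {
      r <- images[[key]]
      if (!with_masks) r$mask <- NULL
      return(r)
    }
    r <- load_radiograph(key, resolution)
    mp <- manifest$mask[i]
    if (with_masks && !is.na(mp) && nzchar(mp))
      r$mask <- load_mask(mp, resolution)
    r
  })
}
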