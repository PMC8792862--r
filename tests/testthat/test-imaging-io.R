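test_that("radiograph loading normalises by the dtype maximum", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "const.png")
  png::writePNG(matrix(1, 8, 8), p1)  # every 8-bit sample at 255
  r <- load_radiograph(p1, 8)
  expect_true(all(r$pixels == 1))
  # 2x2 image with samples {0, 255}, no resampling
  p2 <- file.path(dir, "two.png")
  png::writePNG(matrix(c(0, 0, 1, 1), 2, 2), p2)
  r2 <- load_radiograph(p2, 2)
  expect_equal(r2$pixels, matrix(c(0, 0, 1, 1), 2, 2))
})

test_that("loaded radiographs stay inside the unit interval after resizing", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "noise.png")
  png::writePNG(matrix(runif(64 * 64), 64, 64), p)
  r <- load_radiograph(p, 16)
  expect_equal(dim(r$pixels), c(16, 16))
  expect_gte(min(r$pixels), 0)
  expect_lte(max(r$pixels), 1)
  expect_error(load_radiograph(file.path(dir, "absent.png"), 16), "absent")
})

test_that("mask I/O is binary, nearest-neighbour, and round-trips exactly", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "mask.png")
  set.seed(7)
  m <- random_mask(16, 16)
  save_mask(m, p)
  expect_equal(load_mask(p, 16), m)
  # 8-bit {0, 255} maps to exactly {0, 1}
  expect_true(all(load_mask(p, 16) %in% c(0L, 1L)))
  # nearest-neighbour decimation of a 2x2 block keeps one foreground pixel
  blk <- matrix(0L, 4, 4); blk[1:2, 1:2] <- 1L
  pb <- file.path(dir, "blk.png")
  save_mask(blk, pb)
  small <- load_mask(pb, 2)
  expect_equal(small, matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_equal(sum(small), 1L)
  # all-zero mask stays all-background
  pz <- file.path(dir, "zero.png")
  save_mask(matrix(0L, 8, 8), pz)
  expect_true(all(load_mask(pz, 8) == 0L))
})

test_that("manifests round-trip through CSV with empty mask fields", {
  dir <- withr::local_tempdir()
  m <- data.frame(image = c("a.png", "b.png"), mask = c("a_m.png", ""),
                  pool = c("annotated", "unannotated"),
                  fold = c(1L, 2L), stringsAsFactors = FALSE)
  p <- file.path(dir, "manifest.csv")
  write_manifest(m, p)
  m2 <- read_manifest(p)
  expect_equal(m2$image, m$image)
  expect_equal(m2$mask, m$mask)
  expect_equal(m2$pool, m$pool)
  expect_equal(m2$fold, m$fold)
  bad <- m; bad$mask[1] <- ""
  expect_error(write_manifest(bad, p), class = "usgan_validation_error")
})

test_that("semi-supervised splits stratify annotation within folds", {
  m <- data.frame(image = sprintf("i%03d", 1:100),
                  mask = sprintf("m%03d", 1:100),
                  pool = "annotated", fold = NA_integer_,
                  stringsAsFactors = FALSE)
  s <- make_semisup_splits(m, 0.25, 5, seed = 9)
  expect_setequal(unique(s$fold), 1:5)
  expect_equal(as.vector(table(s$fold)), rep(20L, 5))
  # every training portion of 80 has exactly 20 annotated / 60 unannotated
  for (f in 1:5) {
    tr <- s[s$fold != f, ]
    expect_equal(sum(tr$pool == "annotated"), 20L)
    expect_equal(sum(tr$pool == "unannotated"), 60L)
  }
  # determinism and full-annotation edge case
  expect_identical(s, make_semisup_splits(m, 0.25, 5, seed = 9))
  s2 <- make_semisup_splits(m, 1, 5, seed = 9)
  expect_true(all(s2$pool == "annotated"))
  expect_error(make_semisup_splits(m, 0, 5, 1), class = "usgan_validation_error")
  expect_error(make_semisup_splits(m, 1.2, 5, 1), class = "usgan_validation_error")
  expect_error(make_semisup_splits(m, 0.5, 1, 1), class = "usgan_validation_error")
  expect_error(make_semisup_splits(m[1:3, ], 0.5, 5, 1),
               class = "usgan_validation_error")
})

test_that("domain-adaptation splits follow the 7:1:2 protocol per domain", {
  src <- data.frame(image = sprintf("s%02d", 1:10), mask = sprintf("sm%02d", 1:10),
                    pool = "source", stringsAsFactors = FALSE)
  tgt <- data.frame(image = sprintf("t%02d", 1:10), mask = "",
                    pool = "target", stringsAsFactors = FALSE)
  u <- make_uda_splits(src, tgt, c(0.7, 0.1, 0.2), seed = 3)
  for (pl in c("source", "target")) {
    tab <- table(u$split[u$pool == pl])
    expect_equal(unname(tab[c("train", "val", "test")]), c(7L, 1L, 2L),
                 ignore_attr = TRUE)
  }
  expect_identical(u, make_uda_splits(src, tgt, c(0.7, 0.1, 0.2), seed = 3))
  expect_error(make_uda_splits(src, tgt, c(1, 0, 0)),
               class = "usgan_validation_error")
  expect_error(make_uda_splits(src, tgt, c(0.7, 0.1, 0.1)),
               class = "usgan_validation_error")
  expect_error(make_uda_splits(src[0, ], tgt), class = "usgan_validation_error")
})
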