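test_that("image write/read round-trips pixels exactly on lossless formats", {
  set.seed(4)
  img <- array(sample(0:255, 2 * 2 * 3, TRUE), c(2, 2, 3))
  storage.mode(img) <- "integer"
  f <- withr::local_tempfile(fileext = ".png")
  write_image(img, f)
  expect_identical(read_image(f), img)
  ftif <- withr::local_tempfile(fileext = ".tif")
  write_image(img, ftif)
  expect_identical(read_image(ftif), img)
})

test_that("grayscale images are replicated to three equal channels", {
  g <- matrix(sample(0:255, 16, TRUE), 4, 4)
  f <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(t(g) / 255), f)
  img <- read_image(f)
  expect_equal(dim(img), c(4L, 4L, 3L))
  expect_identical(img[, , 1], img[, , 2])
  expect_identical(img[, , 1], img[, , 3])
})

test_that("unreadable image files raise an error naming the path", {
  f <- withr::local_tempfile(fileext = ".png")
  writeBin(as.raw(1:10), f)
  expect_error(read_image(f), "cannot read image")
  expect_error(read_image("no/such/file.png"), "not found")
})

test_that("label images with values {0,2,3} pass strict validation", {
  lab <- matrix(sample(c(0L, 2L, 3L), 36, TRUE), 6, 6)
  f <- withr::local_tempfile(fileext = ".png")
  write_label_image(lab, f)
  expect_identical(read_label_image(f, strict = TRUE), lab)
})

test_that("strict mode rejects out-of-set label values", {
  f <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(t(matrix(c(0, 1, 2, 3), 2, 2)) / 255), f)
  expect_error(read_label_image(f, strict = TRUE), "outside \\{0,2,3\\}")
})

test_that("non-strict mode remaps to the nearest code, ties to smaller", {
  # value 1 is equidistant from 0 and 2 -> 0; value 5 -> 3; value 100 -> 3
  raw_vals <- matrix(c(0, 1, 5, 100), 2, 2)
  f <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(t(raw_vals) / 255), f)
  expect_warning(lab <- read_label_image(f, strict = FALSE), "remapped")
  expect_identical(lab, matrix(c(0L, 0L, 3L, 3L), 2, 2))
})

test_that("color-coded white/red/green labels decode; other colors error", {
  lab <- matrix(c(0L, 2L, 3L, 0L), 2, 2)
  f <- withr::local_tempfile(fileext = ".png")
  write_image(colorize_labels(lab), f)
  expect_identical(read_label_image(f), lab)
  bad <- array(7L, c(2, 2, 3))
  fb <- withr::local_tempfile(fileext = ".png")
  write_image(bad, fb)
  expect_error(read_label_image(fb), "white/red/green")
})

test_that("ImageJ polygon ROI files parse to absolute vertices", {
  f <- withr::local_tempfile(fileext = ".roi")
  write_roi_fixture(f, x = c(10L, 20L, 15L), y = c(10L, 10L, 20L))
  p <- read_imagej_roi(f)
  expect_equal(p$x, c(10L, 20L, 15L))
  expect_equal(p$y, c(10L, 10L, 20L))
  expect_equal(p$n, 3L)
})

test_that("ROI bounding-box offset is applied to relative vertices", {
  # vertices stored relative to (left = 100, top = 50)
  f <- withr::local_tempfile(fileext = ".roi")
  write_roi_fixture(f, x = c(100L, 140L, 120L), y = c(50L, 50L, 90L))
  p <- read_imagej_roi(f)
  expect_equal(p$x[1], 100L)
  expect_equal(p$y[1], 50L)
})

test_that("bad magic and non-polygon ROI types are rejected", {
  f <- withr::local_tempfile(fileext = ".roi")
  writeBin(c(charToRaw("ABCD"), raw(100)), f)
  expect_error(read_imagej_roi(f), "magic")
  f2 <- withr::local_tempfile(fileext = ".roi")
  write_roi_fixture(f2, x = c(1L, 5L, 3L), y = c(1L, 1L, 4L), type = 2L)
  expect_error(read_imagej_roi(f2), "unsupported ROI type")
})

test_that("package ROI writer round-trips through the reader", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    poly <- list(x = sample(0:2000, n, TRUE), y = sample(0:2000, n, TRUE))
    f <- withr::local_tempfile(fileext = ".roi")
    write_imagej_roi(poly, f)
    p <- read_imagej_roi(f)
    expect_equal(p$x, poly$x)
    expect_equal(p$y, poly$y)
  }
})

test_that("feature tables round-trip through CSV", {
  tab <- make_feature_table(n_per_class = 2, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_true(attr(back, "has_class"))
  expect_equal(back$class, tab$class)
  expect_equal(as.matrix(back[, tma_feature_names()]),
               as.matrix(tab[, tma_feature_names()]), tolerance = 1e-12)
  # without class column
  tab$class <- NULL
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_false(attr(back, "has_class"))
})

test_that("malformed feature tables raise schema errors", {
  tab <- make_feature_table(n_per_class = 2, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab[, 1:10], f)
  expect_error(read_feature_table(f), "lacks column")
  tab2 <- tab
  tab2$R_mean <- as.character(tab2$R_mean)
  tab2$R_mean[1] <- "oops"
  write_feature_table(tab2, f)
  expect_error(read_feature_table(f), "non-numeric")
})

test_that("flat run configuration files parse typed values", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("n_images = 3", "scale = 0.25  # comment",
               "enhancements = equalize, match",
               "out_dir = \"results\"", "strict = true"), f)
  cfg <- read_run_config(f)
  expect_identical(cfg$n_images, 3)
  expect_identical(cfg$scale, 0.25)
  expect_identical(cfg$enhancements, c("equalize", "match"))
  expect_identical(cfg$out_dir, "results")
  expect_true(cfg$strict)
})
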