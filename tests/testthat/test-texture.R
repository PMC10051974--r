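test_that("channel splitting is a lossless decomposition", {
  set.seed(2)
  img <- array(sample(0:255, 48, TRUE), c(4, 4, 3))
  storage.mode(img) <- "integer"
  ch <- split_channels(img)
  expect_named(ch, c("R", "G", "B"))
  recombined <- array(0L, dim(img))
  recombined[, , 1] <- ch$R; recombined[, , 2] <- ch$G
  recombined[, , 3] <- ch$B
  expect_identical(recombined, img)
  red <- array(0L, c(2, 2, 3)); red[, , 1] <- 255L
  chr <- split_channels(red)
  expect_true(all(chr$R == 255) && all(chr$G == 0) && all(chr$B == 0))
})

test_that("first-order statistics match hand-computed values", {
  fo <- first_order_stats(c(1, 2, 3, 4))
  expect_equal(unname(fo["mean"]), 2.5)
  expect_equal(unname(fo["variance"]), 1.25)
  expect_equal(unname(fo["min"]), 1)
  expect_equal(unname(fo["max"]), 4)
  expect_equal(unname(fo["median"]), 2.5)
  expect_equal(unname(fo["range"]), 3)
  # two equal-mass bins -> 1 bit of entropy
  fo2 <- first_order_stats(c(0, 255, 0, 255))
  expect_equal(unname(fo2["entropy"]), 1)
  # constant region degenerates cleanly
  foc <- first_order_stats(rep(7, 10))
  expect_equal(unname(foc[c("variance", "entropy", "skewness", "range")]),
               c(0, 0, 0, 0))
  expect_error(first_order_stats(numeric(0)), "empty")
})

test_that("first-order statistics agree with a brute-force oracle", {
  set.seed(31)
  for (i in 1:1000) {
    x <- sample(0:255, sample(2:60, 1), replace = TRUE)
    got <- first_order_stats(x)
    want <- oracle_first_order(x)
    expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-9)
  }
})

test_that("first-order statistics are permutation invariant", {
  set.seed(32)
  x <- sample(0:255, 40, TRUE)
  expect_equal(first_order_stats(x), first_order_stats(rev(sample(x))))
})

test_that("tamura features degrade gracefully on constant regions", {
  ch <- matrix(100, 16, 16)
  mask <- matrix(TRUE, 16, 16)
  tf <- tamura_features(ch, mask)
  expect_equal(unname(tf["contrast"]), 0)
  expect_equal(unname(tf["roughness"]), unname(tf["coarseness"]))
  expect_error(tamura_features(ch, matrix(FALSE, 16, 16)), "empty mask")
})

test_that("stripe orientation is respected under 90-degree rotation", {
  v <- matrix(rep(c(0, 255), 8), 16, 16)          # vertical stripes
  h <- t(v)                                        # horizontal stripes
  mask <- matrix(TRUE, 16, 16)
  tv <- tamura_features(v, mask)
  th <- tamura_features(h, mask)
  expect_equal(unname(tv["contrast"]), unname(th["contrast"]))
  expect_equal(unname(tv["directionality"]), unname(th["directionality"]),
               tolerance = 1e-8)
  expect_gt(unname(tv["directionality"]), 0.5)     # strongly oriented
})

test_that("a checkerboard has strictly higher contrast than a flat patch", {
  ch <- outer(1:8, 1:8, function(i, j) ifelse((i + j) %% 2 == 0, 0, 255))
  mask <- matrix(TRUE, 8, 8)
  t_check <- tamura_features(ch, mask)
  t_flat <- tamura_features(matrix(128, 8, 8), mask)
  expect_gt(unname(t_check["contrast"]), unname(t_flat["contrast"]))
})

test_that("feature tables have exactly 69 named feature columns", {
  expect_length(tma_feature_names(), 69L)
  expect_equal(length(unique(tma_feature_names())), 69L)
  # 23 per channel
  for (ch in c("R", "G", "B"))
    expect_equal(sum(startsWith(tma_feature_names(), paste0(ch, "_"))), 23L)
  d <- generate_tma(synthetic_params(size = 96, seed = 21))
  m <- slic(d$image, slic_params(grid_size = 16))
  tab <- extract_feature_table(d$image, m, "img")
  expect_equal(nrow(tab), m$K)
  expect_true(all(tma_feature_names() %in% names(tab)))
  expect_true(all(is.finite(as.matrix(tab[, tma_feature_names()]))))
})

test_that("a constant image yields identical first-order rows", {
  img <- array(42L, c(64, 64, 3))
  m <- slic(img, slic_params(grid_size = 16, regularization = 1))
  tab <- extract_feature_table(img, m, "flat")
  fo_cols <- tma_feature_names()[!grepl(
    "coarseness|contrast|directionality|linelikeness|regularity|roughness",
    tma_feature_names())]
  expect_equal(length(fo_cols), 51L)
  for (col in fo_cols)
    expect_equal(length(unique(tab[[col]])), 1L)
})

test_that("feature extraction is deterministic and dimension-checked", {
  d <- generate_tma(synthetic_params(size = 96, seed = 22))
  m <- slic(d$image, slic_params(grid_size = 16))
  t1 <- extract_feature_table(d$image, m, "a")
  t2 <- extract_feature_table(d$image, m, "a")
  expect_identical(t1, t2)
  m_small <- slic(array(0L, c(48, 48, 3)), slic_params(grid_size = 16))
  expect_error(extract_feature_table(d$image, m_small, "a"), "dimensions")
})

test_that("labels attach majority-vote classes to feature rows", {
  d <- generate_tma(synthetic_params(size = 96, seed = 23))
  m <- slic(d$image, slic_params(grid_size = 16))
  tab <- extract_feature_table(d$image, m, "img", labels = d$labels)
  expect_true(all(tab$class %in% c(0L, 2L, 3L)))
  cls <- assign_classes(m, d$labels)
  expect_equal(tab$class, cls$class[match(tab$superpixel_id,
                                          cls$superpixel_id)])
})
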