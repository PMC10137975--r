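test_that("first-order features handle degenerate and two-point images", {
  fo <- first_order_features(matrix(0.5, 6, 6))
  expect_equal(unname(fo), c(0.5, 0, 0, 0, 0))

  img <- matrix(c(0, 0, 1, 1), 2, 2)
  fo <- first_order_features(img, levels = 2L)
  expect_equal(fo[["mean"]], 0.5)
  expect_equal(fo[["sd"]], 0.5)
  expect_equal(fo[["entropy"]], 1)  # one bit for a 50/50 split
})

test_that("first-order moments match the flattened-loop oracle", {
  set.seed(11)
  for (i in 1:5) {
    img <- rand_img(16, 16)
    expect_equal(first_order_features(img, 8L), oracle_first_order(img, 8L),
                 tolerance = 1e-10)
  }
})

test_that("GLCM of a constant image is a single unit entry", {
  q <- quantize(matrix(0.5, 6, 6), 8L)
  g <- compute_glcm(q, glcm_config())
  expect_equal(g[5, 5], 1)  # level 4, 1-based cell (5,5)
  expect_equal(sum(g), 1)
})

test_that("GLCM counts match exhaustive pair enumeration on the 4x4 block image", {
  q <- matrix(c(0L, 0L, 2L, 2L,
                0L, 0L, 2L, 2L,
                1L, 1L, 3L, 3L,
                1L, 1L, 3L, 3L), 4, 4, byrow = TRUE)
  attr(q, "levels") <- 4L
  cfg <- glcm_config(levels = 4L, offsets = list(c(0L, 1L)),
                     symmetric = FALSE, normalize = FALSE)
  g <- compute_glcm(q, cfg)
  expect_equal(unclass(g),
               oracle_glcm(q, 4L, list(c(0L, 1L)), symmetric = FALSE,
                           normalize = FALSE),
               ignore_attr = TRUE)
  expect_equal(attr(g, "pair_count"), 12)  # 3 horizontal pairs per row
})

test_that("GLCM matches enumeration on random images for all default offsets", {
  set.seed(21)
  cfg <- glcm_config()
  for (i in 1:8) {
    q <- quantize(rand_img(16, 16), 8L)
    g <- compute_glcm(q, cfg)
    expect_equal(unclass(g), oracle_glcm(q, 8L, cfg$offsets),
                 ignore_attr = TRUE, tolerance = 1e-14)
    expect_equal(sum(g), 1)
    expect_equal(unclass(g), t(unclass(g)), ignore_attr = TRUE)  # symmetric mode
  }
})

test_that("GLCM rejects invalid inputs", {
  q <- quantize(rand_img(4, 4), 8L)
  expect_error(glcm_config(offsets = list(c(0L, 0L))), "not allowed")
  expect_error(compute_glcm(q, glcm_config(levels = 4L)), "levels")
  big <- glcm_config(offsets = list(c(10L, 0L)))
  expect_error(compute_glcm(quantize(rand_img(4, 4), 8L), big), "no pixel pairs")
})

test_that("GLCM features of degenerate and hand-computable matrices", {
  # constant image: all mass on one diagonal cell
  g <- compute_glcm(quantize(matrix(0.9, 5, 5), 8L), glcm_config())
  f <- glcm_features(g)
  expect_equal(unname(f), c(1, 0, 1, 0, 0))

  # two-cell antidiagonal GLCM: closed-form values
  g2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f2 <- glcm_features(g2)
  expect_equal(f2[["energy"]], 0.5)
  expect_equal(f2[["contrast"]], 1)
  expect_equal(f2[["idm"]], 0.5)
  expect_equal(f2[["dm"]], 1)
  expect_equal(f2[["correlation"]], -1)
})

test_that("GLCM features match the double-loop oracle on random matrices", {
  set.seed(31)
  for (i in 1:10) {
    g <- matrix(runif(64), 8, 8)
    g <- g / sum(g)
    expect_equal(glcm_features(g), oracle_glcm_features(g), tolerance = 1e-12)
  }
  expect_error(glcm_features(matrix(1, 8, 8)), "normalized")
})

test_that("correlation stays within [-1, 1] on random normalized GLCMs", {
  set.seed(41)
  for (i in 1:100) {
    g <- matrix(rexp(36), 6, 6)
    g <- g / sum(g)
    corr <- glcm_features(g)[["correlation"]]
    expect_gte(corr, -1 - 1e-12)
    expect_lte(corr, 1 + 1e-12)
  }
})

test_that("coarseness follows the literal formula and its log form", {
  img <- matrix(1, 2, 2)
  cn <- coarseness(img)
  expect_equal(cn$value, 0.25)        # 2^-4 * 4
  expect_equal(cn$log2, log2(0.25))
  expect_equal(coarseness(matrix(0, 2, 2))$value, 0)
  # at realistic sizes the literal value is vanishingly small; the log
  # form stays on a workable scale and satisfies the arithmetic identity
  big <- matrix(0.5, 255, 255)
  cb <- coarseness(big)
  expect_lt(cb$value, 1e-145)
  expect_equal(cb$log2, log2(sum(big)) - 510)
  huge <- matrix(0.5, 600, 600)
  expect_identical(coarseness(huge)$value, 0)
  expect_true(is.finite(coarseness(huge)$log2))
})

test_that("the feature vector has the fixed 11-name order and degenerate values", {
  fv <- feature_vector(matrix(0.5, 8, 8))
  expect_named(fv, c("mean", "sd", "entropy", "skewness", "kurtosis",
                     "energy", "contrast", "idm", "dm", "correlation",
                     "coarseness"))
  expect_equal(unname(fv[1:10]), c(0.5, 0, 0, 0, 0, 1, 0, 1, 0, 0))
  expect_true(all(is.finite(fv)))
})

test_that("the feature vector is deterministic and transpose-invariant", {
  set.seed(51)
  img <- rand_img(24, 24)
  expect_identical(feature_vector(img), feature_vector(img))
  expect_equal(feature_vector(t(img)), feature_vector(img), tolerance = 1e-12)
})

test_that("tumor and normal phantoms separate in contrast and energy", {
  tum <- test_phantom(seed = 0, tumor = TRUE, noise_sigma = 0.05)$image
  nor <- test_phantom(seed = 0, tumor = FALSE, noise_sigma = 0.05)$image
  ft <- feature_vector(tum); fn <- feature_vector(nor)
  expect_gt(abs(ft[["contrast"]] - fn[["contrast"]]), 1e-3)
  expect_gt(abs(ft[["energy"]] - fn[["energy"]]), 1e-3)
})

test_that("feature_table stacks one row per image", {
  imgs <- list(rand_img(16, 16), rand_img(16, 16))
  tbl <- feature_table(imgs)
  expect_s3_class(tbl, "tbl_df")
  expect_equal(dim(tbl), c(2L, 11L))
})
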