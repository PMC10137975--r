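test_that("fixed thresholding honors its contract", {
  img <- rand_img(8, 8)
  expect_true(!any(threshold_brightness(img, "fixed", t = 1)))
  expect_error(threshold_brightness(img, "fixed"), "requires")
})

test_that("Otsu separates a bimodal image strictly between its modes", {
  img <- matrix(c(rep(0.2, 32), rep(0.8, 32)), 8, 8)
  mask <- threshold_brightness(img, "otsu")
  t <- attr(mask, "threshold")
  expect_gt(t, 0.2); expect_lt(t, 0.8)
  expect_equal(sum(mask), 32)
  expect_true(all(img[mask] == 0.8))
})

test_that("Otsu matches exhaustive between-class-variance search", {
  ramp <- seq(0, 255) / 255
  expect_equal(otsu_threshold(ramp), oracle_otsu(ramp))
  set.seed(81)
  for (i in 1:5) {
    v <- c(rnorm(200, 0.3, 0.05), rnorm(80, 0.75, 0.05))
    v <- pmin(pmax(v, 0), 1)
    expect_equal(otsu_threshold(v), oracle_otsu(v))
  }
})

test_that("opening removes specks and preserves solid squares", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_true(!any(morphological_cleanup(m, 1L)))

  sq <- matrix(FALSE, 11, 11); sq[3:9, 3:9] <- TRUE
  out <- morphological_cleanup(sq, 1L)
  expect_equal(out, sq)
})

test_that("morphological cleanup is idempotent", {
  set.seed(91)
  m <- matrix(runif(400) > 0.6, 20, 20)
  once <- morphological_cleanup(m, 2L)
  expect_equal(morphological_cleanup(once, 2L), once)
})

test_that("largest_component keeps exactly the biggest blob", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:6] <- TRUE   # 10 px
  m[7:8, 7:8] <- TRUE   # 4 px
  out <- largest_component(m)
  expect_equal(sum(out), 10)
  expect_true(all(out[2:3, 2:6]))
  # empty in, empty out
  e <- matrix(FALSE, 5, 5)
  expect_equal(largest_component(e), e)
})

test_that("largest_component agrees with a BFS flood-fill oracle", {
  set.seed(101)
  for (conn in c(4L, 8L)) {
    for (i in 1:10) {
      m <- matrix(runif(15 * 15) > 0.55, 15, 15)
      out <- largest_component(m, connectivity = conn)
      lab <- oracle_label(m, conn)
      if (!any(m)) {
        expect_true(!any(out))
      } else {
        sizes <- tabulate(lab[lab > 0])
        expect_equal(sum(out), max(sizes))
        # the kept pixels form exactly one oracle component
        kept <- unique(lab[out])
        expect_equal(length(kept), 1L)
        expect_equal(sum(lab == kept), sum(out))
      }
    }
  }
})

test_that("diagonally touching blobs merge under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 6, 6)
  m[2:3, 2:3] <- TRUE   # 4 px
  m[4, 4] <- TRUE       # touches only diagonally
  m[6, 6] <- TRUE
  expect_equal(sum(largest_component(m, 8L)), 5)
  expect_equal(sum(largest_component(m, 4L)), 4)
})

test_that("localize_tumor recovers seeded tumors with high Dice", {
  for (s in 1:3) {
    sp <- phantom_spec(seed = s, noise_sigma = 0.03, tumor_delta = 0.3)
    ph <- generate_phantom(sp)
    filt <- anisotropic_filter(contrast_stretch(ph$image),
                               diffusion_params())$image
    res <- localize_tumor(filt, ph$image)
    expect_gte(dice(res$mask, ph$mask), 0.8)
    expect_lte(max(abs(res$centroid - sp$tumor_center)), 3)
    # bbox tightly bounds the mask
    expect_equal(res$bbox,
                 c(min(which(rowSums(res$mask) > 0)),
                   min(which(colSums(res$mask) > 0)),
                   max(which(rowSums(res$mask) > 0)),
                   max(which(colSums(res$mask) > 0))))
    expect_equal(res$area, sum(res$mask))
  }
})

test_that("normal phantoms produce a near-empty tumor mask", {
  for (s in 1:3) {
    ph <- generate_phantom(phantom_spec(seed = 200 + s, tumor = FALSE,
                                        noise_sigma = 0.03))
    filt <- anisotropic_filter(contrast_stretch(ph$image),
                               diffusion_params())$image
    res <- localize_tumor(filt, ph$image)
    head_area <- sum(filt > 0.05)
    expect_lt(res$area, 0.01 * head_area)
  }
})

test_that("Dice never decreases as tumor contrast grows", {
  dd <- vapply(c(0.25, 0.35, 0.45), function(delta) {
    ph <- generate_phantom(phantom_spec(seed = 17, noise_sigma = 0.03,
                                        tumor_delta = delta))
    filt <- anisotropic_filter(contrast_stretch(ph$image),
                               diffusion_params())$image
    dice(localize_tumor(filt, ph$image)$mask, ph$mask)
  }, numeric(1))
  expect_true(all(diff(dd) >= -1e-12))
})

test_that("the overlay only touches boundary pixels of the original", {
  ph <- generate_phantom(phantom_spec(seed = 4, noise_sigma = 0.03))
  filt <- anisotropic_filter(contrast_stretch(ph$image),
                             diffusion_params())$image
  res <- localize_tumor(filt, ph$image)
  changed <- which(res$overlay != ph$image)
  expect_true(all(res$mask[changed]))
  expect_true(all(res$overlay[changed] == 1))
  untouched <- which(res$overlay == ph$image)
  expect_gt(length(untouched), 0.9 * length(ph$image))
})
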