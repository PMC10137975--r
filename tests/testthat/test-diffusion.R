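test_that("conduction is 1 at zero gradient and takes the analytic values at kappa", {
  expect_equal(conduction(0, kappa = 0.1), 1)
  expect_equal(conduction(0, kappa = 0.1, form = "rational"), 1)
  expect_equal(conduction(0.1, kappa = 0.1, form = "exponential"), exp(-1))
  expect_equal(conduction(0.1, kappa = 0.1, form = "rational"), 0.5)
  expect_error(conduction(0.1, kappa = 0), "kappa")
})

test_that("conduction is strictly decreasing and bounded in (0,1]", {
  s <- seq(0, 2, by = 0.05)
  for (form in c("exponential", "rational")) {
    g <- conduction(s, kappa = 0.2, form = form)
    expect_true(all(g > 0 & g <= 1))
    expect_true(all(diff(g) < 0))
  }
})

test_that("an edge diffuses weakly while a small fluctuation diffuses freely", {
  kappa <- 0.1
  for (form in c("exponential", "rational")) {
    at_edge <- conduction(5 * kappa, kappa, form)
    at_noise <- conduction(0.2 * kappa, kappa, form)
    expect_lt(at_edge, at_noise)
    expect_lt(at_edge, 0.1)
    expect_gt(at_noise, 0.9)
  }
})

test_that("a constant image is a fixed point of the diffusion step", {
  img <- matrix(0.6, 6, 6)
  for (ea in c(TRUE, FALSE)) {
    p <- diffusion_params(edge_average = ea)
    expect_equal(diffuse_step(img, p), img)
  }
})

test_that("the default time step is the stability bound 1/4", {
  expect_equal(diffusion_params()$dt, 0.25)
  expect_error(diffusion_params(dt = 0.3), "0.25")
  expect_error(diffusion_params(dt = 0), "0.25")
})

test_that("diffuse_step matches the double-loop reference on random images", {
  set.seed(123)
  for (i in 1:20) {
    m <- sample(5:9, 1); n <- sample(5:9, 1)
    img <- rand_img(m, n)
    for (ea in c(TRUE, FALSE)) for (form in c("exponential", "rational")) {
      p <- diffusion_params(kappa = 0.2, form = form, edge_average = ea)
      expect_lt(max(abs(diffuse_step(img, p) - oracle_diffuse_step(img, p))),
                1e-12)
    }
  }
})

test_that("every output pixel respects the 4-neighborhood extremum principle", {
  set.seed(99)
  p <- diffusion_params(dt = 0.25)
  for (i in 1:25) {
    img <- rand_img(16, 16)
    out <- diffuse_step(img, p)
    lo <- pmin(img, shift_up(img), shift_down(img),
               shift_left(img), shift_right(img))
    hi <- pmax(img, shift_up(img), shift_down(img),
               shift_left(img), shift_right(img))
    expect_true(all(out >= lo - 1e-12 & out <= hi + 1e-12))
  }
})

test_that("variance of a pure-noise image never increases across iterations", {
  set.seed(5)
  img <- matrix(pmin(pmax(rnorm(32 * 32, 0.5, 0.1), 0), 1), 32, 32)
  p <- diffusion_params()
  v <- var(as.numeric(img))
  for (i in 1:15) {
    img <- diffuse_step(img, p)
    v2 <- var(as.numeric(img))
    expect_lte(v2, v + 1e-15)
    v <- v2
  }
})

test_that("a constant nonzero image stops after one iteration with IE 0", {
  res <- anisotropic_filter(matrix(0.5, 8, 8), diffusion_params())
  expect_identical(res$n_iters, 1L)
  expect_equal(res$ie_trace, 0)
})

test_that("an all-zero image stops immediately with IE reported as 0", {
  res <- anisotropic_filter(matrix(0, 8, 8), diffusion_params())
  expect_identical(res$n_iters, 1L)
  expect_equal(res$ie_trace, 0)
})

test_that("filtering the noisy phantom reduces MSE against the clean image", {
  ph <- test_phantom(seed = 0, noise_sigma = 0.05)
  clean <- test_phantom(seed = 0, noise_sigma = 0)$image
  res <- anisotropic_filter(ph$image, diffusion_params())
  expect_lt(mse(res$image, clean), mse(ph$image, clean))
})

test_that("the stopping rule honors its tolerance-or-cap contract", {
  ph <- test_phantom(seed = 0, noise_sigma = 0.05)
  p <- diffusion_params(tol = 1e-4, max_iters = 100L)
  res <- anisotropic_filter(ph$image, p)
  expect_lte(res$n_iters, 100L)
  expect_true(res$ie_trace[res$n_iters] <= 1e-4 || res$n_iters == 100L)
  expect_equal(length(res$ie_trace), res$n_iters)
  # default knee tolerance actually triggers the IE rule
  res2 <- anisotropic_filter(ph$image, diffusion_params())
  expect_lt(res2$n_iters, diffusion_params()$max_iters)
  expect_lte(res2$ie_trace[res2$n_iters], diffusion_params()$tol)
})
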