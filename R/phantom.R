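#' Specification of a synthetic brain phantom
#'
#' Describes one synthetic axial slice: an elliptical "head" of smooth
#' textured tissue on a dark background, optionally carrying a compact
#' hyperintense "tumor" disk with a known ground-truth mask, plus additive
#' Gaussian noise. The defaults are the study conditions used throughout
#' the package's tests: a 128 x 128 working grid, head intensity 0.4 with
#' texture amplitude 0.04, a radius-12 tumor raised by 0.3, and noise
#' sigma 0.05.
#'
#' @param size `c(m, n)` image size in pixels.
#' @param head_axes `c(row_semi_axis, col_semi_axis)` of the head ellipse
#'   in pixels; default 42% of each dimension.
#' @param background head tissue intensity (default 0.4). The surround
#'   outside the head sits at 0.02.
#' @param texture_sigma standard deviation of the smoothed Gaussian
#'   texture field inside the head (default 0.04).
#' @param tumor logical; include a tumor (default `TRUE`).
#' @param tumor_center `c(row, col)`; default offset up-right of the head
#'   center.
#' @param tumor_radius disk radius in pixels (default 12).
#' @param tumor_delta intensity increment of the tumor over the head
#'   tissue (default 0.3); `background + tumor_delta` must stay in (0, 1].
#' @param noise_sigma additive Gaussian noise sigma (default 0.05).
#' @param seed integer RNG seed; the phantom is fully determined by it.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(128L, 128L), head_axes = NULL,
                         background = 0.4, texture_sigma = 0.04,
                         tumor = TRUE, tumor_center = NULL,
                         tumor_radius = 12, tumor_delta = 0.3,
                         noise_sigma = 0.05, seed = 0L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 16L))
    stop("`size` must be c(m, n) with both >= 16", call. = FALSE)
  if (is.null(head_axes)) head_axes <- 0.42 * size
  if (is.null(tumor_center))
    tumor_center <- c(size[1] / 2 - 0.3 * head_axes[1],
                      size[2] / 2 + 0.3 * head_axes[2])
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (background + tumor_delta <= 0 || background + tumor_delta > 1)
    stop("`background + tumor_delta` must lie in (0, 1]", call. = FALSE)
  spec <- structure(list(size = size, head_axes = head_axes,
                         background = background,
                         texture_sigma = texture_sigma, tumor = isTRUE(tumor),
                         tumor_center = tumor_center,
                         tumor_radius = tumor_radius,
                         tumor_delta = tumor_delta,
                         noise_sigma = noise_sigma,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  if (spec$tumor) {
    ctr <- c(size[1] / 2, size[2] / 2)
    # conservative inscribed check: shrink each semi-axis by the radius
    d <- sum(((spec$tumor_center - ctr) /
                pmax(head_axes - tumor_radius, 1e-9))^2)
    if (any(head_axes <= tumor_radius) || d > 1)
      stop("tumor disk does not fit inside the head ellipse", call. = FALSE)
  }
  spec
}

# separable Gaussian smoothing with replicate padding
gaussian_smooth <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  m <- nrow(x); n <- ncol(x)
  padr <- x[c(rep(1L, r), seq_len(m), rep(m, r)), , drop = FALSE]
  y <- apply(padr, 2, function(col) stats::filter(col, k)[(r + 1):(r + m)])
  pady <- y[, c(rep(1L, r), seq_len(n), rep(n, r)), drop = FALSE]
  t(apply(pady, 1, function(row) stats::filter(row, k)[(r + 1):(r + n)]))
}

#' Generate one synthetic brain phantom
#'
#' Renders the slice described by a [phantom_spec()]: dark surround at
#' 0.02, head ellipse at `background` plus a Gaussian-smoothed texture
#' field (smoothing sigma 3 px, rescaled to `texture_sigma` inside the
#' head), optionally a tumor disk raised by `tumor_delta` with a 2-px
#' linear soft outer edge, then additive Gaussian noise and a clip to
#' `[0, 1]`. The ground-truth mask is the hard disk (distance to center
#' `<= tumor_radius`). Bitwise reproducible from `spec$seed`.
#'
#' @param spec a [phantom_spec()] object.
#' @return an object of class `phantom`: list with `image` (grayscale
#'   matrix), `mask` (logical ground truth, empty when no tumor), `label`
#'   (1 abnormal / 0 normal) and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  m <- spec$size[1]; n <- spec$size[2]
  rr <- matrix(seq_len(m), m, n)
  cc <- matrix(seq_len(n), m, n, byrow = TRUE)
  head <- ((rr - m / 2) / spec$head_axes[1])^2 +
    ((cc - n / 2) / spec$head_axes[2])^2 <= 1
  img <- matrix(0.02, m, n)
  tex <- gaussian_smooth(matrix(rnorm(m * n), m, n), sigma = 3)
  s <- sd(tex[head])
  if (spec$texture_sigma > 0 && s > 0) {
    tex <- tex / s * spec$texture_sigma
  } else {
    tex <- tex * 0
  }
  img[head] <- spec$background + tex[head]
  mask <- matrix(FALSE, m, n)
  if (spec$tumor) {
    d <- sqrt((rr - spec$tumor_center[1])^2 + (cc - spec$tumor_center[2])^2)
    w <- pmin(1, pmax(0, (spec$tumor_radius + 2 - d) / 2))
    img <- img + spec$tumor_delta * w
    mask <- d <= spec$tumor_radius
  }
  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(m * n, sd = spec$noise_sigma), m, n)
  structure(list(image = clip01(img), mask = mask,
                 label = as.integer(spec$tumor), spec = spec),
            class = "phantom")
}

# derived per-index seeds, kept inside 32-bit integer range
substream_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) * 10007 + index * 7919 + salt * 104729) %%
               2147483647)
}

#' Generate a labeled phantom dataset
#'
#' Produces `n_abnormal` tumor-bearing and `n_normal` tumor-free phantoms
#' (abnormal first). Each image draws its tumor parameters from an
#' independent substream seeded by `(seed, index)`, so image `i` is stable
#' under changes of the dataset size: tumor intensity delta uniform in
#' `delta_range`, radius uniform in `radius_range`, and center jittered
#' uniformly within +-10 px of the base position (kept inside the head).
#'
#' @param n_abnormal,n_normal class counts; their sum must be >= 2.
#' @param base_spec a [phantom_spec()] giving the shared geometry, noise
#'   level and texture.
#' @param seed integer master seed.
#' @param delta_range,radius_range jitter ranges for the tumor contrast
#'   and radius.
#' @return an object of class `phantom_dataset`: list with `images`,
#'   `masks`, `labels` (integer 1/0), `ids` and `specs`.
#' @export
generate_dataset <- function(n_abnormal, n_normal,
                             base_spec = phantom_spec(), seed = 0L,
                             delta_range = c(0.25, 0.35),
                             radius_range = c(9, 15)) {
  n_abnormal <- as.integer(n_abnormal); n_normal <- as.integer(n_normal)
  if (is.na(n_abnormal) || is.na(n_normal) || n_abnormal < 0L ||
      n_normal < 0L || n_abnormal + n_normal < 2L)
    stop("need non-negative class counts summing to >= 2", call. = FALSE)
  ntot <- n_abnormal + n_normal
  labels <- c(rep(1L, n_abnormal), rep(0L, n_normal))
  images <- vector("list", ntot)
  masks <- vector("list", ntot)
  specs <- vector("list", ntot)
  ctr <- base_spec$size / 2
  for (i in seq_len(ntot)) {
    set.seed(substream_seed(seed, i))
    spec_i <- base_spec
    spec_i$seed <- substream_seed(seed, i, salt = 1L)
    if (labels[i] == 1L) {
      spec_i$tumor <- TRUE
      spec_i$tumor_delta <- runif(1, delta_range[1], delta_range[2])
      spec_i$tumor_radius <- runif(1, radius_range[1], radius_range[2])
      repeat {
        cand <- base_spec$tumor_center + runif(2, -10, 10)
        d <- sum(((cand - ctr) /
                    pmax(base_spec$head_axes - spec_i$tumor_radius, 1e-9))^2)
        if (d <= 1) break
      }
      spec_i$tumor_center <- cand
    } else {
      spec_i$tumor <- FALSE
    }
    ph <- generate_phantom(spec_i)
    images[[i]] <- ph$image
    masks[[i]] <- ph$mask
    specs[[i]] <- spec_i
  }
  structure(list(images = images, masks = masks, labels = labels,
                 ids = sprintf("phantom_%03d", seq_len(ntot)), specs = specs),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d images (%d abnormal, %d normal), %dx%d\n",
              length(x$images), sum(x$labels == 1L), sum(x$labels == 0L),
              nrow(x$images[[1]]), ncol(x$images[[1]])))
  invisible(x)
}
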