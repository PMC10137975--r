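#' Configuration for gray-level co-occurrence matrices
#'
#' @param levels number of quantized gray levels `L >= 2` (default 8).
#' @param offsets list of `c(drow, dcol)` pixel displacements; default the
#'   four canonical distance-1 directions (horizontal, vertical and the
#'   two diagonals). `(0, 0)` is not allowed.
#' @param symmetric if `TRUE` (default) each ordered pair is also counted
#'   in the transposed cell, making the matrix symmetric.
#' @param normalize if `TRUE` (default) counts are divided by the total
#'   pair count so entries sum to 1.
#' @return an object of class `glcm_config`.
#' @export
glcm_config <- function(levels = 8L,
                        offsets = list(c(0L, 1L), c(1L, 0L),
                                       c(1L, 1L), c(1L, -1L)),
                        symmetric = TRUE, normalize = TRUE) {
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("`levels` must be >= 2", call. = FALSE)
  if (!is.list(offsets) || length(offsets) == 0L)
    stop("`offsets` must be a non-empty list of c(drow, dcol)", call. = FALSE)
  for (o in offsets) {
    if (length(o) != 2L || any(o != round(o)))
      stop("each offset must be two integers", call. = FALSE)
    if (all(o == 0L)) stop("offset (0, 0) is not allowed", call. = FALSE)
  }
  structure(list(levels = levels, offsets = lapply(offsets, as.integer),
                 symmetric = isTRUE(symmetric), normalize = isTRUE(normalize)),
            class = "glcm_config")
}

#' First-order intensity statistics
#'
#' Population moments of the raw intensities plus histogram entropy: the
#' mean, the population standard deviation, the Shannon entropy in bits of
#' the `levels`-bin normalized intensity histogram (with `0 log 0 := 0`),
#' and the standardized third and fourth central moments (skewness, and
#' raw — not excess — kurtosis). On a constant image the standard
#' deviation is 0 and skewness and kurtosis are returned as 0 by
#' convention.
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @param levels number of histogram bins for the entropy (default 8).
#' @return named numeric vector `(mean, sd, entropy, skewness, kurtosis)`.
#' @export
first_order_features <- function(img, levels = 8L) {
  assert_gray_image(img)
  v <- as.numeric(img)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  p <- tabulate(as.integer(quantize(img, levels)) + 1L, nbins = levels)
  p <- p / sum(p)
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  if (s > 0) {
    sk <- mean((v - m)^3) / s^3
    ku <- mean((v - m)^4) / s^4
  } else {
    sk <- 0
    ku <- 0
  }
  c(mean = m, sd = s, entropy = ent, skewness = sk, kurtosis = ku)
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of quantized gray levels
#' `(v(r, c), v(r + drow, c + dcol))` over every in-bounds pixel pair and
#' every configured offset, accumulated into one `L x L` matrix. In
#' symmetric mode the transposed pair is counted too; in normalized mode
#' the matrix is divided by the total pair count.
#'
#' @param qimg integer matrix of gray levels from [quantize()] (values
#'   must be `< config$levels`).
#' @param config a [glcm_config()] object.
#' @return an `L x L` matrix of class `glcm` with attributes `config` and
#'   `pair_count` (total number of counted pairs, transposed pairs
#'   included).
#' @export
compute_glcm <- function(qimg, config = glcm_config()) {
  if (!is.matrix(qimg) || !is.numeric(qimg))
    stop("`qimg` must be an integer matrix", call. = FALSE)
  L <- config$levels
  if (any(qimg < 0L) || any(qimg >= L))
    stop("`qimg` values must lie in [0, levels - 1]", call. = FALSE)
  m <- nrow(qimg); n <- ncol(qimg)
  counts <- matrix(0, L, L)
  any_pairs <- FALSE
  for (off in config$offsets) {
    dr <- off[1]; dc <- off[2]
    rows <- seq_len(m)[seq_len(m) + dr >= 1L & seq_len(m) + dr <= m]
    cols <- seq_len(n)[seq_len(n) + dc >= 1L & seq_len(n) + dc <= n]
    if (length(rows) == 0L || length(cols) == 0L) next
    any_pairs <- TRUE
    a <- qimg[rows, cols, drop = FALSE]
    b <- qimg[rows + dr, cols + dc, drop = FALSE]
    idx <- as.integer(a) * L + as.integer(b) + 1L
    counts <- counts + matrix(tabulate(idx, nbins = L * L),
                              L, L, byrow = TRUE)
  }
  if (!any_pairs)
    stop("image too small for every configured offset: no pixel pairs",
         call. = FALSE)
  if (config$symmetric) counts <- counts + t(counts)
  pair_count <- sum(counts)
  g <- if (config$normalize) counts / pair_count else counts
  structure(g, class = c("glcm", "matrix"), config = config,
            pair_count = pair_count)
}

#' Haralick-style features of a normalized GLCM
#'
#' With `p(x, y)` the normalized co-occurrence probability of gray levels
#' `x, y` in `0 .. L-1`:
#' energy (angular second moment) `sum p^2`; contrast
#' `sum (x - y)^2 p`; inverse difference moment (homogeneity)
#' `sum p / (1 + (x - y)^2)`; directional moment `sum |x - y| p`; and
#' correlation `sum (x - Mx)(y - My) p / (sx * sy)` with marginal means
#' and standard deviations `Mx, My, sx, sy`. A degenerate GLCM with
#' `sx * sy = 0` returns correlation 0 by convention.
#'
#' @param g a normalized [compute_glcm()] matrix.
#' @return named numeric vector `(energy, contrast, idm, dm, correlation)`.
#' @export
glcm_features <- function(g) {
  if (!is.matrix(g)) stop("`g` must be a GLCM matrix", call. = FALSE)
  if (abs(sum(g) - 1) > 1e-8)
    stop("`g` must be normalized (entries summing to 1)", call. = FALSE)
  L <- nrow(g)
  lev <- seq_len(L) - 1
  x <- matrix(lev, L, L)        # row level
  y <- matrix(lev, L, L, byrow = TRUE)  # col level
  en <- sum(g^2)
  con <- sum((x - y)^2 * g)
  idm <- sum(g / (1 + (x - y)^2))
  dm <- sum(abs(x - y) * g)
  px <- rowSums(g); py <- colSums(g)
  mx <- sum(lev * px); my <- sum(lev * py)
  sx <- sqrt(sum((lev - mx)^2 * px)); sy <- sqrt(sum((lev - my)^2 * py))
  corr <- if (sx * sy > 0) sum((x - mx) * (y - my) * g) / (sx * sy) else 0
  c(energy = en, contrast = con, idm = idm, dm = dm, correlation = corr)
}

#' Coarseness of an image texture
#'
#' The granularity summary `Cness = 2^-(m+n) * sum f(x, y)`. At realistic
#' image sizes the literal value is astronomically small (around 1e-150
#' for 255x255, underflowing to exactly 0 once `m + n` exceeds the double
#' exponent range), so the base-2 logarithm `log2(sum f) - (m + n)` is
#' returned alongside it; the assembled [feature_vector()] carries the log
#' form. An alternative reading of the prefactor as `1 / (2 (m + n))`
#' exists but is deliberately not implemented.
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @return list with `value` (literal, possibly underflowed to 0) and
#'   `log2` (finite log-scale form; the zero-sum image maps to the
#'   smallest representable magnitude rather than `-Inf`).
#' @export
coarseness <- function(img) {
  assert_gray_image(img)
  s <- sum(img)
  mn <- nrow(img) + ncol(img)
  list(value = 2^(-mn) * s,
       log2 = log2(max(s, 1e-300)) - mn)
}

#' The fixed-order 11-feature texture descriptor
#'
#' Quantizes the image, builds the offset-averaged symmetric normalized
#' GLCM, and assembles the descriptor used by the classifier, in fixed
#' order: mean, sd, entropy, skewness, kurtosis (first-order); energy,
#' contrast, idm, dm, correlation (GLCM); coarseness (log2 form, see
#' [coarseness()]). Deterministic in its inputs.
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @param config a [glcm_config()] object (its `levels` also sets the
#'   entropy histogram bins).
#' @return named numeric vector of length 11.
#' @export
feature_vector <- function(img, config = glcm_config()) {
  fo <- first_order_features(img, config$levels)
  g <- compute_glcm(quantize(img, config$levels), config)
  gf <- glcm_features(g)
  c(fo, gf, coarseness = coarseness(img)$log2)
}

#' Feature table for a list of images
#'
#' Applies [feature_vector()] to each image and stacks the results.
#'
#' @param images list of grayscale matrices.
#' @param config a [glcm_config()] object.
#' @return a tibble with one row per image and the 11 feature columns.
#' @export
feature_table <- function(images, config = glcm_config()) {
  rows <- t(vapply(images, feature_vector, numeric(11), config = config))
  tibble::as_tibble(as.data.frame(rows))
}
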