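#' tumorscan: brain MRI tumor recognition pipeline
#'
#' Contrast stretching, anisotropic diffusion denoising, GLCM texture
#' features, quality metrics, morphological tumor localization and
#' Gaussian-kernel SVM classification, exercised end to end on seeded
#' synthetic brain phantoms with known ground truth.
#'
#' Throughout the package a grayscale image is an ordinary numeric matrix
#' with `m` rows and `n` columns, intensities in `[0, 1]`, indexed
#' `img[row, col]` (row-major, top-left origin). All functions share this
#' convention.
#'
#' @keywords internal
#' @importFrom stats quantile rnorm runif sd var predict
"_PACKAGE"

# ---- GrayImage validation ---------------------------------------------------

#' Validate a grayscale image matrix
#'
#' Checks that `img` is a numeric matrix of at least 2x2 with all values
#' finite and in `[0, 1]` — the contract every pipeline stage relies on.
#'
#' @param img object to check.
#' @param arg name used in error messages.
#' @return `img`, invisibly, if valid; otherwise an error is thrown.
#' @export
assert_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(img) < 2L || ncol(img) < 2L)
    stop(sprintf("`%s` must be at least 2x2", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  rng <- range(img)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop(sprintf("`%s` has intensities outside [0, 1]", arg), call. = FALSE)
  invisible(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Load an image file as a grayscale intensity matrix
#'
#' Reads a raster image (PNG, JPEG, TIFF; any format EBImage can decode),
#' converts multi-channel data to a single channel with the luminance
#' weighted sum `0.299 R + 0.587 G + 0.114 B`, normalizes intensities to
#' `[0, 1]` (8-bit values are divided by 255, 16-bit by 65535 — EBImage
#' performs this scaling on read), and optionally resizes with bilinear
#' interpolation. DICOM is not supported.
#'
#' @param path path to the image file.
#' @param target_size optional `c(rows, cols)` output size; bilinear resize
#'   followed by a clip to `[0, 1]`.
#' @return numeric matrix (rows x cols) with values in `[0, 1]`.
#' @export
load_image <- function(path, target_size = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("`path` must name an existing file", call. = FALSE)
  if (file.size(path) == 0L)
    stop("`path` is an empty file", call. = FALSE)
  eb <- tryCatch(EBImage::readImage(path),
                 error = function(e) stop("unreadable or unsupported image file: ",
                                          conditionMessage(e), call. = FALSE))
  dat <- EBImage::imageData(eb)
  if (length(dim(dat)) == 3L) {
    nc <- dim(dat)[3]
    dat <- if (nc >= 3L) {
      0.299 * dat[, , 1] + 0.587 * dat[, , 2] + 0.114 * dat[, , 3]
    } else {
      dat[, , 1]
    }
  }
  # EBImage stores images [x, y]; transpose to the package's [row, col]
  img <- t(dat)
  if (!is.null(target_size))
    img <- resize_bilinear(img, target_size[1], target_size[2])
  clip01(img)
}

#' Bilinear resize of a grayscale matrix
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param out_m,out_n output rows and columns.
#' @return resized matrix, clipped to `[0, 1]`.
#' @export
resize_bilinear <- function(img, out_m, out_n) {
  assert_gray_image(img)
  eb <- EBImage::resize(EBImage::Image(img), w = out_m, h = out_n,
                        filter = "bilinear")
  clip01(EBImage::imageData(eb))
}

#' Quantize a grayscale image to discrete gray levels
#'
#' Maps intensity `v` in `[0, 1]` to integer level `min(floor(v * L), L - 1)`,
#' a monotone non-decreasing binning into `L` levels `0 .. L-1` — the discrete
#' representation the co-occurrence matrix is built on.
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @param levels integer number of gray levels `L >= 2`.
#' @return integer matrix of levels in `[0, L-1]` with attribute `"levels"`.
#' @export
quantize <- function(img, levels = 8L) {
  assert_gray_image(img)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L)
    stop("`levels` must be an integer >= 2", call. = FALSE)
  q <- pmin(floor(img * levels), levels - 1L)
  storage.mode(q) <- "integer"
  attr(q, "levels") <- levels
  q
}
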