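check_same_dim <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("images must have identical dimensions", call. = FALSE)
}

#' Mean squared error between two images
#'
#' `(1/(m*n)) * sum (a - b)^2`; symmetric and non-negative.
#'
#' @param a,b grayscale matrices of identical size.
#' @return scalar squared-intensity error.
#' @export
mse <- function(a, b) {
  assert_gray_image(a, "a"); assert_gray_image(b, "b")
  check_same_dim(a, b)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' Intensities are scaled to the integer range of the given bit depth,
#' `[0, 2^n - 1]`, and `PSNR = 20 log10((2^n - 1) / sqrt(MSE_scaled))`.
#' Identical images (zero MSE) return `Inf`. Note the standard inverse
#' relation: larger MSE means lower PSNR.
#'
#' @param a,b grayscale matrices of identical size.
#' @param bit_depth integer bit depth `n >= 1` (default 8).
#' @return PSNR in dB (`Inf` when `a == b`).
#' @export
psnr <- function(a, b, bit_depth = 8L) {
  if (bit_depth < 1L) stop("`bit_depth` must be >= 1", call. = FALSE)
  err <- mse(a, b)
  if (err == 0) return(Inf)
  peak <- 2^bit_depth - 1
  20 * log10(peak / sqrt(err * peak^2))
}

# sums of x over all w x w windows fully inside the image (integral image)
box_sums <- function(x, w) {
  m <- nrow(x); n <- ncol(x)
  cs <- rbind(0, apply(x, 2, cumsum))
  v <- cs[(w + 1):(m + 1), , drop = FALSE] - cs[1:(m - w + 1), , drop = FALSE]
  cs2 <- cbind(0, t(apply(v, 1, cumsum)))
  cs2[, (w + 1):(n + 1), drop = FALSE] - cs2[, 1:(n - w + 1), drop = FALSE]
}

#' Structural similarity index
#'
#' Standard two-term SSIM over a sliding square window (uniform weights,
#' population variances): per window
#' `(2 mu_x mu_y + C1)(2 cov_xy + C2) / ((mu_x^2 + mu_y^2 + C1)(s_x^2 + s_y^2 + C2))`
#' with `C1 = (k1 L)^2`, `C2 = (k2 L)^2` and dynamic range `L = 1`. The
#' returned value is the mean over all fully interior windows;
#' `ssim(x, x) = 1` and the measure is symmetric.
#'
#' @param a,b grayscale matrices of identical size.
#' @param window sliding window side in pixels (default 8; must not exceed
#'   either image dimension).
#' @param k1,k2 stabilization constants (defaults 0.01 and 0.03).
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, window = 8L, k1 = 0.01, k2 = 0.03) {
  assert_gray_image(a, "a"); assert_gray_image(b, "b")
  check_same_dim(a, b)
  w <- as.integer(window)
  if (w < 2L || w > min(dim(a)))
    stop("`window` must be in [2, min(m, n)]", call. = FALSE)
  np <- w * w
  c1 <- k1^2; c2 <- k2^2
  mu_a <- box_sums(a, w) / np
  mu_b <- box_sums(b, w) / np
  va <- box_sums(a^2, w) / np - mu_a^2
  vb <- box_sums(b^2, w) / np - mu_b^2
  cab <- box_sums(a * b, w) / np - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * cab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (va + vb + c2)
  mean(num / den)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`, ranging from 0 (disjoint) to 1 (identical).
#' Two empty masks agree perfectly on absence and return 1 with a warning.
#'
#' @param a,b logical matrices of identical size.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!is.logical(a) || !is.logical(b))
    stop("masks must be logical matrices", call. = FALSE)
  check_same_dim(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

#' Full quality report between a reference and a test image
#'
#' @param ref,test grayscale matrices of identical size.
#' @param mask_ref,mask_test optional logical masks scored by [dice()].
#' @param bit_depth bit depth for [psnr()].
#' @return one-row tibble with columns `ssim`, `mse`, `psnr` and (when
#'   masks are supplied) `dice`.
#' @export
quality_report <- function(ref, test, mask_ref = NULL, mask_test = NULL,
                           bit_depth = 8L) {
  out <- tibble::tibble(ssim = ssim(ref, test),
                        mse = mse(ref, test),
                        psnr = psnr(ref, test, bit_depth))
  if (!is.null(mask_ref) && !is.null(mask_test))
    out$dice <- dice(mask_ref, mask_test)
  out
}
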