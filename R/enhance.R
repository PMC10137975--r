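#' Percentile contrast stretching
#'
#' Linearly maps the occupied intensity range onto `[0, 1]`: with `a` and
#' `b` the `low_pct` and `high_pct` intensity percentiles, each pixel
#' becomes `clip((v - a) / (b - a), 0, 1)`. Relative gray-level ordering is
#' preserved within `[a, b]`; no histogram equalization is performed. The
#' defaults `(0, 100)` give a pure min-max stretch; tighter percentiles are
#' useful on real MRI with hot pixels.
#'
#' A constant image (where `b == a`) cannot be stretched; it is returned as
#' an all-zero image with a warning.
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @param low_pct,high_pct percentiles in `[0, 100]` with
#'   `low_pct < high_pct` defining the input range to map.
#' @return stretched grayscale matrix in `[0, 1]`, with the `(a, b)` input
#'   range recorded in attribute `"range"` so the same mapping can be
#'   replayed on a reference image.
#' @export
contrast_stretch <- function(img, low_pct = 0, high_pct = 100) {
  assert_gray_image(img)
  if (!(low_pct >= 0 && high_pct <= 100 && low_pct < high_pct))
    stop("require 0 <= low_pct < high_pct <= 100", call. = FALSE)
  a <- unname(quantile(img, low_pct / 100))
  b <- unname(quantile(img, high_pct / 100))
  if (b <= a) {
    warning("constant intensity range; returning all-zero image")
    out <- matrix(0, nrow(img), ncol(img))
    attr(out, "range") <- c(a, a)
    return(out)
  }
  out <- clip01((img - a) / (b - a))
  attr(out, "range") <- c(a, b)
  out
}
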