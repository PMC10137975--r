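#' Otsu threshold over a set of intensities
#'
#' Builds an `n_bins`-bin histogram of the supplied intensities on
#' `[0, 1]` and exhaustively picks the bin boundary maximizing the
#' between-class variance `w0 w1 (mu0 - mu1)^2`. Accepting a plain vector
#' (rather than only a whole image) lets the caller restrict the histogram
#' to a region of interest, e.g. the head ellipse.
#'
#' @param values numeric vector of intensities in `[0, 1]`.
#' @param n_bins histogram resolution (default 256).
#' @return threshold intensity `t` in `(0, 1)`; pixels with value `> t`
#'   form the bright class.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  if (length(values) == 0L || !all(is.finite(values)))
    stop("`values` must be a non-empty finite vector", call. = FALSE)
  bins <- pmin(floor(values * n_bins), n_bins - 1L) + 1L
  h <- tabulate(bins, nbins = n_bins)
  p <- h / sum(h)
  lev <- (seq_len(n_bins) - 0.5) / n_bins   # bin centers
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[n_bins]
  # candidate thresholds: upper edge of bins 1 .. n_bins-1
  w0 <- w0[-n_bins]; mu0s <- mu[-n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0s[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)
  k / n_bins
}

#' Brightness thresholding of an image
#'
#' Categorizes pixel brightness into a binary mask `img > t`, with `t`
#' either fixed or chosen by Otsu's between-class-variance criterion over
#' a 256-bin histogram.
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param t threshold intensity in `[0, 1]`; required for
#'   `method = "fixed"`.
#' @param region optional logical matrix; when given, the Otsu histogram
#'   is computed from pixels inside this region only (the mask itself is
#'   still evaluated over the whole image).
#' @return logical matrix with attribute `"threshold"` recording `t`.
#' @export
threshold_brightness <- function(img, method = c("otsu", "fixed"), t = NULL,
                                 region = NULL) {
  assert_gray_image(img)
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(t) || !is.numeric(t) || t < 0 || t > 1)
      stop("fixed thresholding requires `t` in [0, 1]", call. = FALSE)
  } else {
    vals <- if (is.null(region)) as.numeric(img) else img[region]
    t <- otsu_threshold(vals)
  }
  mask <- img > t
  attr(mask, "threshold") <- t
  mask
}

as_mask <- function(eb_data) {
  m <- eb_data > 0.5
  storage.mode(m) <- "logical"
  m
}

#' Morphological cleanup of a binary mask
#'
#' Binary opening (removes specks smaller than the structuring element)
#' followed by closing (fills comparably small holes), both with a disk
#' structuring element of the given radius.
#'
#' @param mask logical matrix.
#' @param se_radius disk radius in pixels, >= 1 (default 2).
#' @return cleaned logical matrix of the same size.
#' @export
morphological_cleanup <- function(mask, se_radius = 2L) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (se_radius < 1L) stop("`se_radius` must be >= 1", call. = FALSE)
  brush <- EBImage::makeBrush(2L * as.integer(se_radius) + 1L, shape = "disc")
  x <- EBImage::Image(mask * 1)
  x <- EBImage::closing(EBImage::opening(x, brush), brush)
  as_mask(EBImage::imageData(x))
}

# union-find for merging 4-connected labels across diagonal adjacencies
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Keep only the largest connected component
#'
#' Labels the foreground with 4- or 8-connectivity and retains the
#' component with the most pixels. Ties are broken in favor of the
#' component whose first pixel comes earliest in row-major scan order.
#' An empty mask is returned unchanged.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return logical matrix containing only the winning component.
#' @export
largest_component <- function(mask, connectivity = 8L) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  if (!any(mask)) return(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    m <- nrow(lab); n <- ncol(lab)
    parent <- seq_len(nlab)
    # diagonal neighbor pairs (down-right and down-left)
    pairs <- rbind(
      cbind(as.integer(lab[-m, -n]), as.integer(lab[-1, -1])),
      cbind(as.integer(lab[-m, -1]), as.integer(lab[-1, -n])))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs) > 0L) {
      for (i in seq_len(nrow(pairs))) {
        ra <- uf_find(parent, pairs[i, 1]); rb <- uf_find(parent, pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(nlab), function(i) uf_find(parent, i), integer(1))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  if (length(cand) > 1L) {
    # row-major scan order of each candidate's first pixel
    first_pos <- vapply(cand, function(l) {
      idx <- which(lab == l)
      rr <- (idx - 1L) %% nrow(lab) + 1L
      cc <- (idx - 1L) %/% nrow(lab) + 1L
      min((rr - 1L) * ncol(lab) + cc)
    }, integer(1))
    cand <- cand[which.min(first_pos)]
  }
  lab == cand[1]
}

#' Segmentation configuration for tumor localization
#'
#' @param method thresholding method, `"otsu"` (default) or `"fixed"`.
#' @param t fixed threshold (only with `method = "fixed"`).
#' @param se_radius disk radius for morphological cleanup (default 2).
#' @param connectivity component connectivity, 4 or 8 (default 8).
#' @param head_floor intensity above which a pixel counts as head rather
#'   than background (default 0.05); the threshold histogram is restricted
#'   to head pixels so the dark surround cannot skew it.
#' @param head_erode radius (pixels) by which the head region is eroded
#'   before building the threshold histogram (default 3). Denoising
#'   smears the head boundary into a ring of intermediate intensities;
#'   without the erosion, Otsu locks onto the ring-versus-interior split
#'   instead of tissue-versus-tumor.
#' @param z_guard minimum threshold expressed as the head median plus this
#'   many robust standard deviations (`1.4826 * MAD`; default 2.5). On a
#'   tumor-free head Otsu has no bright mode to find and would bisect the
#'   texture; the guard keeps such splits above the texture's own spread.
#'   The median/MAD form is insensitive to the tumor itself inflating the
#'   statistics. Set `NULL` to disable.
#' @return an object of class `segment_config`.
#' @export
segment_config <- function(method = c("otsu", "fixed"), t = NULL,
                           se_radius = 2L, connectivity = 8L,
                           head_floor = 0.05, head_erode = 3L,
                           z_guard = 2.5) {
  structure(list(method = match.arg(method), t = t,
                 se_radius = as.integer(se_radius),
                 connectivity = as.integer(connectivity),
                 head_floor = head_floor, head_erode = as.integer(head_erode),
                 z_guard = z_guard),
            class = "segment_config")
}

mask_bbox <- function(mask) {
  if (!any(mask)) return(rep(NA_integer_, 4L))
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  c(rr[1], cc[1], rr[2], cc[2])
}

boundary_pixels <- function(mask) {
  inner <- mask &
    shift_up(mask) & shift_down(mask) & shift_left(mask) & shift_right(mask)
  mask & !inner
}

#' Localize a tumor on a filtered image
#'
#' The localization chain: brightness threshold on the filtered image
#' (Otsu restricted to the eroded head region, floored by the robust
#' z-score guard), morphological opening/closing with a disk, retention of the largest
#' connected component, and an overlay of the component boundary burned
#' at full intensity into the original image.
#'
#' @param filtered denoised grayscale matrix the mask is derived from.
#' @param original grayscale matrix of the same size the overlay is drawn
#'   on.
#' @param cfg a [segment_config()] object.
#' @return an object of class `tumor_result`: list with `mask` (logical),
#'   `bbox` (`c(row0, col0, row1, col1)`, 1-based inclusive; `NA`s when
#'   empty), `centroid` (`c(row, col)` fractional pixels; `NA`s when
#'   empty), `area` (pixel count), `threshold` (intensity used) and
#'   `overlay`.
#' @export
localize_tumor <- function(filtered, original, cfg = segment_config()) {
  assert_gray_image(filtered, "filtered")
  assert_gray_image(original, "original")
  check_same_dim(filtered, original)
  head <- filtered > cfg$head_floor
  if (cfg$method == "fixed") {
    mask <- threshold_brightness(filtered, "fixed", t = cfg$t)
  } else {
    interior <- head
    if (cfg$head_erode >= 1L) {
      brush <- EBImage::makeBrush(2L * cfg$head_erode + 1L, shape = "disc")
      interior <- as_mask(EBImage::imageData(
        EBImage::erode(EBImage::Image(head * 1), brush)))
    }
    hv <- filtered[interior]
    if (length(hv) == 0L) hv <- filtered[head]
    if (length(hv) == 0L) hv <- as.numeric(filtered)
    t0 <- otsu_threshold(hv)
    if (!is.null(cfg$z_guard))
      t0 <- max(t0, stats::median(hv) +
                  cfg$z_guard * 1.4826 * stats::mad(hv, constant = 1))
    mask <- filtered > t0
    attr(mask, "threshold") <- t0
  }
  thr <- attr(mask, "threshold")
  mask <- (mask & head)
  mask <- morphological_cleanup(mask, cfg$se_radius)
  mask <- largest_component(mask, cfg$connectivity)
  area <- sum(mask)
  bbox <- mask_bbox(mask)
  centroid <- if (area > 0) {
    idx <- which(mask)
    c(mean((idx - 1L) %% nrow(mask) + 1L),
      mean((idx - 1L) %/% nrow(mask) + 1L))
  } else {
    c(NA_real_, NA_real_)
  }
  overlay <- original
  overlay[boundary_pixels(mask)] <- 1
  structure(list(mask = mask, bbox = bbox, centroid = centroid, area = area,
                 threshold = thr, overlay = overlay),
            class = "tumor_result")
}

#' @export
print.tumor_result <- function(x, ...) {
  if (x$area == 0) {
    cat("<tumor_result> no region found\n")
  } else {
    cat(sprintf(
      "<tumor_result> area %d px, centroid (%.1f, %.1f), bbox rows %d..%d cols %d..%d, threshold %.3f\n",
      x$area, x$centroid[1], x$centroid[2],
      x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4], x$threshold))
  }
  invisible(x)
}
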