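# Independent brute-force reference implementations used as oracles.
# All are deliberately written as naive per-pixel loops, structurally
# unrelated to the vectorized package code they check.

# one diffusion sweep, straight from the discrete update rule
oracle_diffuse_step <- function(img, params) {
  m <- nrow(img); n <- ncol(img)
  g <- function(s) {
    if (params$form == "exponential") exp(-(s / params$kappa)^2)
    else 1 / (1 + (s / params$kappa)^2)
  }
  at <- function(r, c) img[min(max(r, 1), m), min(max(c, 1), n)]
  cpix <- NULL
  if (params$edge_average) {
    cpix <- matrix(0, m, n)
    for (r in seq_len(m)) for (c in seq_len(n)) {
      gx <- (at(r, c + 1) - at(r, c - 1)) / 2
      gy <- (at(r + 1, c) - at(r - 1, c)) / 2
      cpix[r, c] <- g(sqrt(gx^2 + gy^2))
    }
  }
  out <- img
  nb <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (r in seq_len(m)) for (c in seq_len(n)) {
    acc <- 0
    for (d in nb) {
      rn <- min(max(r + d[1], 1), m); cn <- min(max(c + d[2], 1), n)
      delta <- img[rn, cn] - img[r, c]
      coef <- if (params$edge_average) (cpix[r, c] + cpix[rn, cn]) / 2
              else g(abs(delta))
      acc <- acc + coef * delta
    }
    out[r, c] <- img[r, c] + params$dt * acc
  }
  out
}

# exhaustive ordered-pair enumeration for the co-occurrence matrix
oracle_glcm <- function(qimg, levels, offsets, symmetric = TRUE,
                        normalize = TRUE) {
  m <- nrow(qimg); n <- ncol(qimg)
  counts <- matrix(0, levels, levels)
  for (off in offsets) {
    for (r in seq_len(m)) for (c in seq_len(n)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= m && c2 >= 1 && c2 <= n) {
        a <- qimg[r, c] + 1L; b <- qimg[r2, c2] + 1L
        counts[a, b] <- counts[a, b] + 1
        if (symmetric) counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  if (normalize) counts / sum(counts) else counts
}

# direct double sums of the five GLCM features
oracle_glcm_features <- function(g) {
  L <- nrow(g)
  en <- 0; con <- 0; idm <- 0; dm <- 0
  px <- rowSums(g); py <- colSums(g)
  mx <- 0; my <- 0
  for (i in 1:L) { mx <- mx + (i - 1) * px[i]; my <- my + (i - 1) * py[i] }
  sx <- 0; sy <- 0
  for (i in 1:L) {
    sx <- sx + (i - 1 - mx)^2 * px[i]
    sy <- sy + (i - 1 - my)^2 * py[i]
  }
  sx <- sqrt(sx); sy <- sqrt(sy)
  corr_num <- 0
  for (i in 1:L) for (j in 1:L) {
    x <- i - 1; y <- j - 1; p <- g[i, j]
    en <- en + p^2
    con <- con + (x - y)^2 * p
    idm <- idm + p / (1 + (x - y)^2)
    dm <- dm + abs(x - y) * p
    corr_num <- corr_num + (x - mx) * (y - my) * p
  }
  corr <- if (sx * sy > 0) corr_num / (sx * sy) else 0
  c(energy = en, contrast = con, idm = idm, dm = dm, correlation = corr)
}

# flattened-loop first-order moments
oracle_first_order <- function(img, levels) {
  v <- as.numeric(img); nn <- length(v)
  m <- sum(v) / nn
  s <- sqrt(sum((v - m)^2) / nn)
  h <- rep(0, levels)
  for (x in v) {
    k <- min(floor(x * levels), levels - 1) + 1
    h[k] <- h[k] + 1
  }
  p <- h / nn
  ent <- 0
  for (pi in p) if (pi > 0) ent <- ent - pi * log2(pi)
  if (s > 0) {
    sk <- sum((v - m)^3) / nn / s^3
    ku <- sum((v - m)^4) / nn / s^4
  } else { sk <- 0; ku <- 0 }
  c(mean = m, sd = s, entropy = ent, skewness = sk, kurtosis = ku)
}

# BFS flood-fill connected-component labeling
oracle_label <- function(mask, connectivity = 8L) {
  m <- nrow(mask); n <- ncol(mask)
  lab <- matrix(0L, m, n)
  nb <- if (connectivity == 8L) {
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  cur <- 0L
  for (r0 in seq_len(m)) for (c0 in seq_len(n)) {
    if (mask[r0, c0] && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nb))) {
          r <- p[1] + nb$dr[k]; c <- p[2] + nb$dc[k]
          if (r >= 1 && r <= m && c >= 1 && c <= n &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue <- c(queue, list(c(r, c)))
          }
        }
      }
    }
  }
  lab
}

# exhaustive between-class-variance maximization over all 256-bin
# histogram thresholds, with class weights/means accumulated by loops
oracle_otsu <- function(values, n_bins = 256L) {
  h <- rep(0, n_bins)
  for (x in values) {
    k <- min(floor(x * n_bins), n_bins - 1) + 1
    h[k] <- h[k] + 1
  }
  centers <- ((1:n_bins) - 0.5) / n_bins
  best <- -Inf; best_t <- NA_real_
  for (k in 1:(n_bins - 1)) {
    n0 <- sum(h[1:k]); n1 <- sum(h[(k + 1):n_bins])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[1:k] * centers[1:k]) / n0
    mu1 <- sum(h[(k + 1):n_bins] * centers[(k + 1):n_bins]) / n1
    w0 <- n0 / (n0 + n1); w1 <- 1 - w0
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-12) { best <- sb; best_t <- k / n_bins }
  }
  best_t
}

# random test image in [0,1]
rand_img <- function(m, n) matrix(runif(m * n), m, n)

# small noisy tumor phantom shared by several tests
test_phantom <- function(seed = 0, tumor = TRUE, noise_sigma = 0.05, ...) {
  generate_phantom(phantom_spec(seed = seed, tumor = tumor,
                                noise_sigma = noise_sigma, ...))
}
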