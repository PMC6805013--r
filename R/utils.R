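# shared numeric helpers

#' Otsu threshold of an intensity matrix
#'
#' Between-class-variance threshold on a 256-bin histogram, delegated to
#' [EBImage::otsu()]. A degenerate (single-valued) histogram yields `NA`,
#' which callers treat as "segment nothing" rather than picking an
#' arbitrary cut.
#'
#' @param x numeric matrix (or array) of intensities.
#' @param levels number of histogram bins.
#' @return scalar threshold, or `NA_real_` for a degenerate histogram.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    return(NA_real_)
  }
  EBImage::otsu(EBImage::Image(x), range = rng, levels = levels)
}

#' Three-class Otsu threshold
#'
#' Maximizes the between-class variance over two cut points on a 256-bin
#' histogram and returns the lower cut. For biosensor images that carry a
#' dim background, a mid-intensity cell body, and a small very bright
#' polarized focus, the two-class criterion tends to isolate the focus;
#' the three-class lower threshold separates background from cell instead.
#'
#' @inheritParams otsu_threshold
#' @return the lower of the two thresholds, or `NA_real_` for a degenerate
#'   histogram.
#' @export
otsu3_threshold <- function(x, levels = 256L) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    return(NA_real_)
  }
  br <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(levels + 1)]) / 2
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  best <- -Inf
  k1_best <- 1L
  for (k1 in seq_len(levels - 2)) {
    w1 <- cw[k1]
    if (w1 <= 0) next
    m1 <- cm[k1] / w1
    k2 <- seq(k1 + 1L, levels - 1L)
    w2 <- cw[k2] - w1
    w3 <- 1 - cw[k2]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m2 <- (cm[k2] - cm[k1]) / w2
    m3 <- (cm[levels] - cm[k2]) / w3
    mu <- cm[levels]
    v <- w1 * (m1 - mu)^2 + w2 * (m2 - mu)^2 + w3 * (m3 - mu)^2
    v[!ok] <- -Inf
    i <- which.max(v)
    if (v[i] > best) {
      best <- v[i]
      k1_best <- k1
    }
  }
  br[k1_best + 1L]
}

# run `code` under a temporary RNG seed without touching global RNG state
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# vectorized bilinear interpolation of matrix `img` at (row, col) positions
# given in 1-based pixel-center coordinates; outside the grid -> NA
bilinear <- function(img, r, c) {
  H <- nrow(img)
  W <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= H & c >= 1 & c <= W & is.finite(r) & is.finite(c)
  r0 <- pmin(pmax(floor(r[ok]), 1L), H - 1L)
  c0 <- pmin(pmax(floor(c[ok]), 1L), W - 1L)
  fr <- r[ok] - r0
  fc <- c[ok] - c0
  v00 <- img[cbind(r0, c0)]
  v10 <- img[cbind(r0 + 1L, c0)]
  v01 <- img[cbind(r0, c0 + 1L)]
  v11 <- img[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  out
}

# separable Gaussian smoothing of a position x time map: circular along the
# (periodic) position axis, edge-replicated along time
gauss_smooth_map <- function(mat, sigma_pos, sigma_time) {
  smooth1 <- function(m, sigma, circular) {
    if (sigma <= 0) return(m)
    hw <- max(1L, ceiling(3 * sigma))
    k <- exp(-(seq(-hw, hw))^2 / (2 * sigma^2))
    k <- k / sum(k)
    n <- nrow(m)
    if (circular) {
      idx <- ((seq(1 - hw, n + hw) - 1L) %% n) + 1L
    } else {
      idx <- pmin(pmax(seq(1 - hw, n + hw), 1L), n)
    }
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2 * hw + 1)) {
      out <- out + k[j] * mp[seq_len(n) + (j - 1L), , drop = FALSE]
    }
    out
  }
  mat <- smooth1(mat, sigma_pos, circular = TRUE)
  t(smooth1(t(mat), sigma_time, circular = FALSE))
}

# circular mean of positions given as fractions of the circle, in [0, 1)
circular_mean_frac <- function(frac) {
  ang <- 2 * pi * frac
  m <- atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)
  m %% 1
}

# circular absolute distance between fractions, result in [0, 0.5]
circular_dist_frac <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

# mean and two-sided t-interval; CI is NA for n < 2
t_ci <- function(x, conf = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) {
    return(c(mean = NA_real_, lo = NA_real_, hi = NA_real_, n = 0))
  }
  m <- mean(x)
  if (n < 2) {
    return(c(mean = m, lo = NA_real_, hi = NA_real_, n = n))
  }
  half <- qt(1 - (1 - conf) / 2, df = n - 1) * sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half, n = n)
}

# signed polygon area (shoelace); positive for counter-clockwise orientation
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}
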