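#' Dice overlap coefficient of two binary masks
#'
#' `2|X & Y| / (|X| + |Y|)`. Two empty masks score 1 (agreement on
#' absence); the statistic is symmetric and lies in \[0, 1\].
#'
#' @param x,y Logical (or 0/1) arrays of equal shape.
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' dice(matrix(c(TRUE, TRUE, FALSE), 1), matrix(c(TRUE, FALSE, FALSE), 1))
dice <- function(x, y) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y))) {
    abort("`x` and `y` must have the same shape")
  }
  x <- as.logical(x); y <- as.logical(y)
  tot <- sum(x) + sum(y)
  if (tot == 0) return(1)
  2 * sum(x & y) / tot
}

# Valid-region box means of a matrix: (H-win+1) x (W-win+1) window averages
# via integral images. Matches a uniform filter away from the borders.
box_means_valid <- function(m, win) {
  h <- nrow(m); w <- ncol(m)
  ii <- matrix(0, h + 1L, w + 1L)
  ii[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r1 <- 1:(h - win + 1L); c1 <- 1:(w - win + 1L)
  (ii[r1 + win, c1 + win, drop = FALSE] - ii[r1, c1 + win, drop = FALSE] -
      ii[r1 + win, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]) / (win * win)
}

# Separable Gaussian blur with reflected edges (kernel radius 3*sigma).
gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  refl <- function(idx, n) { idx[idx < 1] <- 2 - idx[idx < 1]; idx[idx > n] <- 2 * n - idx[idx > n]; idx }
  out <- matrix(0, h, w)
  for (d in -r:r) out <- out + k[d + r + 1] * m[refl(seq_len(h) + d, h), , drop = FALSE]
  m2 <- out
  out <- matrix(0, h, w)
  for (d in -r:r) out <- out + k[d + r + 1] * m2[, refl(seq_len(w) + d, w), drop = FALSE]
  out
}

#' Mean structural similarity (SSIM) between two images
#'
#' Windowed SSIM with a uniform sliding window (default 7 px), constants
#' `C1 = (k1 L)^2`, `C2 = (k2 L)^2`, sample-variance normalization, and the
#' border (where the window would leave the image) excluded, then averaged.
#' The dynamic range `L` defaults to the joint max - min of both images
#' ("estimated from the images"). An optional Gaussian pre-blur of both
#' inputs absorbs pixel-level differences between nearly aligned images.
#' Identical images score exactly 1; values lie in \[-1, 1\].
#'
#' @param x,y Numeric matrices of equal shape, min dimension >= `window`.
#' @param window Odd window edge >= 3 (default 7).
#' @param k1,k2 Stability constants (defaults 0.01, 0.03).
#' @param data_range Dynamic range `L`; default estimated from the images.
#' @param pre_blur_sigma Gaussian pre-blur sigma in pixels (0 = off).
#' @return Scalar mean SSIM.
#' @export
ssim <- function(x, y, window = 7L, k1 = 0.01, k2 = 0.03,
                 data_range = NULL, pre_blur_sigma = 0) {
  if (!is.matrix(x) || !is.matrix(y) || !identical(dim(x), dim(y))) {
    abort("`x` and `y` must be numeric matrices of equal shape")
  }
  if (window %% 2 != 1 || window < 3) abort("`window` must be odd and >= 3")
  if (min(dim(x)) < window) abort("images must be at least `window` pixels in each dimension")
  if (k1 <= 0 || k2 <= 0) abort("`k1` and `k2` must be > 0")
  x <- x * 1.0; y <- y * 1.0
  if (is.null(data_range)) {
    data_range <- max(x, y) - min(x, y)
    if (data_range == 0) data_range <- 1 # identical constants: degenerate range
  }
  if (data_range <= 0) abort("`data_range` must be > 0")
  if (pre_blur_sigma > 0) {
    x <- gauss_blur(x, pre_blur_sigma)
    y <- gauss_blur(y, pre_blur_sigma)
  }
  np <- window * window
  cov_norm <- np / (np - 1) # sample covariance
  ux <- box_means_valid(x, window)
  uy <- box_means_valid(y, window)
  uxx <- box_means_valid(x * x, window)
  uyy <- box_means_valid(y * y, window)
  uxy <- box_means_valid(x * y, window)
  vx <- cov_norm * (uxx - ux * ux)
  vy <- cov_norm * (uyy - uy * uy)
  vxy <- cov_norm * (uxy - ux * uy)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  s <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
    ((ux * ux + uy * uy + c1) * (vx + vy + c2))
  mean(s)
}

#' Spearman rank correlation
#'
#' Midranks are used for ties. A constant vector makes the correlation
#' undefined; this is flagged with a warning and `NA` is returned.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return Correlation in \[-1, 1\], or `NA` for constant input.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: Spearman correlation is undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Mann-Whitney U test (two-sided)
#'
#' `U` counts pairs `(a, b)` with `a > b`, plus 1/2 per tie. The p-value
#' uses the exact null distribution when both groups are untied and the
#' smaller group has at most 8 observations, and the normal approximation
#' with continuity and tie corrections otherwise.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return One-row tibble: `u`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  rk <- rank(c(a, b))
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  if (!has_ties && min(na, nb) <= 8) {
    method <- "exact"
    p <- if (u > na * nb / 2) {
      2 * pwilcox(u - 1, na, nb, lower.tail = FALSE)
    } else {
      2 * pwilcox(u, na, nb)
    }
    p <- min(1, p)
  } else {
    method <- "normal approximation"
    n <- na + nb
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sigma
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  tibble(u = u, p_value = p, n_a = na, n_b = nb, method = method)
}
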