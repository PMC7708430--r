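# Stain-deconvolution normalization baselines (Macenko, Vahadane-style).
# Both estimate a 3x2 stain matrix in optical density (OD) space from tissue
# pixels, express each pixel as nonnegative concentrations of the two
# stains, rescale concentrations to a reference's percentile scale, and
# rebuild the image with the reference stain matrix.

rgb_to_od <- function(px) -log(pmax(px, 1) / 255)
od_to_rgb <- function(od) clip255(255 * exp(-od))

tissue_pixels <- function(image, bg) {
  tissue <- !bg
  if (!any(tissue)) abort("no tissue pixels: image is entirely background")
  cbind(image[, , 1][tissue], image[, , 2][tissue], image[, , 3][tissue])
}

# Macenko geometry: project OD onto the top-2 principal plane and take the
# extreme directions (alpha / 100-alpha angle percentiles) as the stains.
estimate_stains_macenko <- function(od, beta = 0.15, alpha = 1) {
  keep <- sqrt(rowSums(od^2)) > beta
  if (sum(keep) < 10) abort("too few stained pixels for stain estimation")
  od <- od[keep, , drop = FALSE]
  ev <- eigen(stats::cov(od), symmetric = TRUE)
  if (ev$values[2] < 1e-8 * max(ev$values[1], 1e-12)) {
    abort("optical-density matrix is rank-deficient: cannot separate two stains")
  }
  v <- ev$vectors[, 1:2]
  proj <- od %*% v
  phi <- atan2(proj[, 2], proj[, 1])
  a1 <- quantile(phi, alpha / 100); a2 <- quantile(phi, 1 - alpha / 100)
  s1 <- v %*% c(cos(a1), sin(a1)); s2 <- v %*% c(cos(a2), sin(a2))
  if (sum(s1) < 0) s1 <- -s1
  if (sum(s2) < 0) s2 <- -s2
  m <- cbind(as.vector(s1), as.vector(s2))
  m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  # convention: hematoxylin-like stain (higher red-channel OD) first
  if (m[1, 1] < m[1, 2]) m <- m[, 2:1]
  m
}

# Vahadane-style: 2-component NMF of the OD matrix by multiplicative
# updates with an L1 sparsity penalty on concentrations, seeded from the
# Macenko estimate so the factorization is deterministic.
estimate_stains_vahadane <- function(od, beta = 0.15, lambda = 0.1, n_iter = 120) {
  keep <- sqrt(rowSums(od^2)) > beta
  if (sum(keep) < 10) abort("too few stained pixels for stain estimation")
  v <- pmax(od[keep, , drop = FALSE], 0)
  m0 <- estimate_stains_macenko(od, beta)
  hmat <- t(m0)                                  # 2 x 3 stain basis
  wmat <- pmax(v %*% m0 %*% solve(crossprod(m0)), 1e-6)
  for (it in seq_len(n_iter)) {
    wmat <- wmat * (v %*% t(hmat)) / (wmat %*% hmat %*% t(hmat) + lambda + 1e-12)
    hmat <- hmat * (t(wmat) %*% v) / (t(wmat) %*% wmat %*% hmat + 1e-12)
  }
  m <- t(hmat)
  m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  if (m[1, 1] < m[1, 2]) m <- m[, 2:1]
  m
}

stain_concentrations <- function(od, m) {
  pmax(od %*% m %*% solve(crossprod(m)), 0)
}

#' Stain-deconvolution reference from an image
#'
#' Estimates the two-stain (hematoxylin/eosin) basis of a reference image in
#' optical-density space together with its 99th-percentile concentration
#' scale, for use by [normalize_macenko()] / [normalize_vahadane()].
#'
#' @param image H x W x 3 array, 0-255.
#' @param bg Background mask; defaults to [background_mask()] of `image`.
#' @param method `"macenko"` (SVD extreme-angle geometry) or `"vahadane"`
#'   (sparse NMF).
#' @return Object of class `stain_ref`: `stain_matrix` (3 x 2, unit
#'   columns), `max_conc` (length 2), `method`.
#' @export
stain_ref <- function(image, bg = background_mask(image),
                      method = c("macenko", "vahadane")) {
  assert_image(image)
  method <- match.arg(method)
  od <- rgb_to_od(tissue_pixels(image, bg))
  m <- switch(method,
              macenko = estimate_stains_macenko(od),
              vahadane = estimate_stains_vahadane(od))
  conc <- stain_concentrations(od, m)
  structure(list(stain_matrix = m,
                 max_conc = apply(conc, 2, quantile, 0.99),
                 method = method),
            class = "stain_ref")
}

# Shared transfer step: estimate the source's own stain matrix with the
# reference's method, rescale concentrations, rebuild with the reference
# basis. Background pixels are returned unchanged.
stain_transfer <- function(image, ref, bg = background_mask(image)) {
  assert_image(image)
  if (!inherits(ref, "stain_ref")) abort("`ref` must be a stain_ref()")
  assert_mask(bg, image, "bg")
  tissue <- !bg
  px <- tissue_pixels(image, bg)
  od <- rgb_to_od(px)
  m_src <- switch(ref$method,
                  macenko = estimate_stains_macenko(od),
                  vahadane = estimate_stains_vahadane(od))
  conc <- stain_concentrations(od, m_src)
  src_max <- apply(conc, 2, quantile, 0.99)
  src_max[src_max <= 0] <- 1
  conc <- sweep(conc, 2, ref$max_conc / src_max, "*")
  out_px <- od_to_rgb(conc %*% t(ref$stain_matrix))
  out <- image
  for (ch in 1:3) {
    chan <- out[, , ch]
    chan[tissue] <- out_px[, ch]
    out[, , ch] <- chan
  }
  out
}

#' Macenko stain normalization
#'
#' @inheritParams reinhard_normalize
#' @param ref A [stain_ref()] with `method = "macenko"`.
#' @return Normalized image; background pixels unchanged.
#' @export
normalize_macenko <- function(image, ref, bg = background_mask(image)) {
  if (!inherits(ref, "stain_ref") || ref$method != "macenko") {
    abort('`ref` must be stain_ref(..., method = "macenko")')
  }
  stain_transfer(image, ref, bg)
}

#' Vahadane-style stain normalization (sparse NMF)
#'
#' @inheritParams reinhard_normalize
#' @param ref A [stain_ref()] with `method = "vahadane"`.
#' @return Normalized image; background pixels unchanged.
#' @export
normalize_vahadane <- function(image, ref, bg = background_mask(image)) {
  if (!inherits(ref, "stain_ref") || ref$method != "vahadane") {
    abort('`ref` must be stain_ref(..., method = "vahadane")')
  }
  stain_transfer(image, ref, bg)
}
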