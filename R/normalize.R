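#' Background (non-tissue) mask of an H&E image
#'
#' A pixel is background when *all* of its RGB values strictly exceed the
#' threshold (default 200 on the 8-bit scale), i.e. near-white glass.
#'
#' @param image H x W x 3 array, 0-255.
#' @param threshold Intensity threshold; strict `>` applies.
#' @return Logical H x W matrix, `TRUE` = background.
#' @export
#' @examples
#' img <- array(250, c(2, 2, 3))
#' img[1, 1, ] <- c(120, 80, 140)
#' background_mask(img)
background_mask <- function(image, threshold = 200) {
  assert_image(image)
  m <- pmin(image[, , 1], pmin(image[, , 2], image[, , 3])) > threshold
  matrix(m, dim(image)[1], dim(image)[2])
}

# sRGB (0-255) <-> decorrelated color space used by Reinhard transfer.
# "lab": CIELAB (D65) via grDevices::convertColor. "lalphabeta": Ruderman's
# l-alpha-beta space (the original color-transfer dialect), log-LMS based.
RUDERMAN_RGB2LMS <- matrix(c(0.3811, 0.5783, 0.0402,
                             0.1967, 0.7244, 0.0782,
                             0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
RUDERMAN_LMS2LAB <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)

rgb_to_decorrelated <- function(px, space) {
  if (space == "lab") {
    grDevices::convertColor(px / 255, from = "sRGB", to = "Lab")
  } else {
    lms <- pmax(px / 255, 1e-6) %*% t(RUDERMAN_RGB2LMS)
    log10(pmax(lms, 1e-6)) %*% t(RUDERMAN_LMS2LAB)
  }
}

decorrelated_to_rgb <- function(dc, space) {
  if (space == "lab") {
    out <- grDevices::convertColor(dc, from = "Lab", to = "sRGB", clip = TRUE)
  } else {
    lms <- 10^(dc %*% t(solve(RUDERMAN_LMS2LAB)))
    out <- lms %*% t(solve(RUDERMAN_RGB2LMS))
  }
  clip255(out * 255)
}

#' White-point gain correction
#'
#' Rescales each channel so the image's white point (a high quantile,
#' default 99.5%) maps to `target` (default 255). Glass background then
#' sits at the top of the intensity scale regardless of global staining or
#' illumination gains, which keeps the absolute background rule (all RGB >
#' 200) meaningful; a global per-channel stain shift is exactly inverted.
#' Gains are clamped to `[min_gain, max_gain]` so images with little
#' background are not over-corrected.
#'
#' @param image H x W x 3 array, 0-255.
#' @param target White-point target intensity.
#' @param q Quantile used as the white-point estimate.
#' @param min_gain,max_gain Clamp on the per-channel gains.
#' @return Corrected image (values clipped to \[0, 255\], not rounded).
#' @export
white_balance <- function(image, target = 255, q = 0.995,
                          min_gain = 2 / 3, max_gain = 1.5) {
  assert_image(image)
  out <- image
  for (ch in 1:3) {
    wp <- quantile(image[, , ch], q, names = FALSE)
    gain <- if (wp > 0) target / wp else 1
    gain <- min(max_gain, max(min_gain, gain))
    out[, , ch] <- out[, , ch] * gain
  }
  clip255(out)
}

#' Reinhard reference statistics of an image's tissue pixels
#'
#' Per-channel mean and standard deviation in a decorrelated color space,
#' computed over tissue (non-background) pixels only, so glass does not pull
#' the statistics toward white.
#'
#' @param image H x W x 3 array, 0-255.
#' @param bg Background mask (defaults to [background_mask()] of the image).
#' @param space `"lab"` (CIELAB, default) or `"lalphabeta"` (Ruderman).
#' @return Object of class `reinhard_stats`: list with `means`, `sds`
#'   (length-3 numerics) and `space`.
#' @export
reinhard_stats <- function(image, bg = background_mask(image), space = c("lab", "lalphabeta")) {
  assert_image(image)
  assert_mask(bg, image, "bg")
  space <- match.arg(space)
  tissue <- !bg
  if (!any(tissue)) abort("no tissue pixels: image is entirely background")
  px <- cbind(image[, , 1][tissue], image[, , 2][tissue], image[, , 3][tissue])
  dc <- rgb_to_decorrelated(px, space)
  structure(list(means = colMeans(dc),
                 sds = apply(dc, 2, sd),
                 space = space),
            class = "reinhard_stats")
}

#' Reinhard color normalization to reference statistics
#'
#' Tissue pixels are transformed channel-wise in the decorrelated space as
#' `(v - mu_src) * (sd_ref / sd_src) + mu_ref`, then converted back to sRGB
#' and clipped to \[0, 255\]. Background pixels are returned unchanged. A
#' zero-variance source channel is mapped to the reference mean.
#'
#' @param image H x W x 3 array, 0-255.
#' @param ref A `reinhard_stats` object (see [reinhard_stats()]).
#' @param bg Background mask; defaults to [background_mask()] of `image`.
#' @return Normalized image, same shape; background pixels identical to the
#'   input.
#' @export
reinhard_normalize <- function(image, ref, bg = background_mask(image)) {
  assert_image(image)
  if (!inherits(ref, "reinhard_stats")) abort("`ref` must be reinhard_stats()")
  assert_mask(bg, image, "bg")
  tissue <- !bg
  if (!any(tissue)) abort("no tissue pixels: image is entirely background")
  px <- cbind(image[, , 1][tissue], image[, , 2][tissue], image[, , 3][tissue])
  dc <- rgb_to_decorrelated(px, ref$space)
  mu_src <- colMeans(dc)
  sd_src <- apply(dc, 2, sd)
  for (ch in 1:3) {
    if (sd_src[ch] <= .Machine$double.eps) {
      dc[, ch] <- ref$means[ch]
    } else {
      dc[, ch] <- (dc[, ch] - mu_src[ch]) * (ref$sds[ch] / sd_src[ch]) + ref$means[ch]
    }
  }
  out_px <- decorrelated_to_rgb(dc, ref$space)
  out <- image
  for (ch in 1:3) {
    chan <- out[, , ch]
    chan[tissue] <- out_px[, ch]
    out[, , ch] <- chan
  }
  out
}

#' Crop-wise stain normalization with overlap blending
#'
#' Applies a normalizer independently on intermediate-sized overlapping
#' crops (default 5000 px, 50% overlap) and blends overlapping regions by
#' unweighted averaging. Normalizing crop-by-crop corrects staining that is
#' uneven *within* one section, which whole-image normalization cannot.
#' Crops that contain no tissue are passed through unchanged; background
#' pixels are always returned exactly as in the input. An image smaller than
#' one crop degrades to whole-image normalization (with a notice).
#'
#' @param image H x W x 3 array, 0-255.
#' @param ref Reference: `reinhard_stats` for `method = "reinhard"`, a
#'   [stain_ref()] for `"macenko"`/`"vahadane"`.
#' @param crop_size Crop edge in pixels (default 5000).
#' @param overlap Fractional overlap between neighboring crops, in \[0, 1).
#' @param method One of `"reinhard"`, `"macenko"`, `"vahadane"`.
#' @param bg_threshold Background threshold (strict `>`, default 200).
#' @param quiet Suppress the small-image notice.
#' @return Normalized image, same shape as the input.
#' @export
normalize_by_crops <- function(image, ref, crop_size = 5000, overlap = 0.5,
                               method = c("reinhard", "macenko", "vahadane"),
                               bg_threshold = 200, quiet = FALSE) {
  assert_image(image)
  method <- match.arg(method)
  assert_scalar_in(overlap, 0, 1 - 1e-9, "overlap")
  h <- dim(image)[1]; w <- dim(image)[2]
  if (!quiet && h <= crop_size && w <= crop_size) {
    inform("image smaller than one crop; using whole-image normalization")
  }
  stride <- max(1L, as.integer(round(crop_size * (1 - overlap))))
  grid <- plan_grid(h, w, tile_size = crop_size, stride = stride, quiet = TRUE)
  bg <- background_mask(image, bg_threshold)
  acc <- array(0, dim(image))
  cnt <- matrix(0L, h, w)
  normalizer <- switch(method,
    reinhard = function(crop, crop_bg) reinhard_normalize(crop, ref, crop_bg),
    macenko = function(crop, crop_bg) stain_transfer(crop, ref, crop_bg),
    vahadane = function(crop, crop_bg) stain_transfer(crop, ref, crop_bg)
  )
  for (k in seq_len(nrow(grid$tiles))) {
    ri <- grid$tiles$row_start[k] + seq_len(grid$tile_h)
    cj <- grid$tiles$col_start[k] + seq_len(grid$tile_w)
    crop <- image[ri, cj, , drop = FALSE]
    crop_bg <- bg[ri, cj, drop = FALSE]
    norm_crop <- if (all(crop_bg)) crop else normalizer(crop, crop_bg)
    acc[ri, cj, ] <- acc[ri, cj, , drop = FALSE] + norm_crop
    cnt[ri, cj] <- cnt[ri, cj] + 1L
  }
  out <- acc / as.vector(cnt)  # cnt recycles across the 3 channels
  for (ch in 1:3) {
    chan <- out[, , ch]
    chan[bg] <- image[, , ch][bg]
    out[, , ch] <- chan
  }
  out
}
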