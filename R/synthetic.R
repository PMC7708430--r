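#' Specification for a synthetic H&E-like sample
#'
#' Describes one synthetic tissue image: its size, the target composition of
#' the cellular region over the four tissue classes, the number and geometry
#' of ductal lesions, and the staining artefacts to emulate (uneven staining
#' within the image, a color shift relative to other images, pixel noise).
#'
#' Target fractions are fractions of the *cellular* (non-background) region.
#' They may sum to less than 1; the remainder shrinks the cellular footprint
#' (more white background) and the fractions are renormalized over what
#' remains cellular.
#'
#' @param height,width Image size in pixels.
#' @param target_fractions Named numeric vector with entries `acinar`, `adm`,
#'   `dysplasia`, `other`; each in \[0, 1\], summing to at most 1.
#' @param n_lesions Number of ductal lesions per ductal class (adm,
#'   dysplasia).
#' @param lumen_fraction Fraction of each ductal lesion's disk left as a
#'   background-colored lumen, in \[0, 0.9\].
#' @param unevenness_amplitude Relative amplitude of the smooth multiplicative
#'   staining gradient applied to tissue pixels, in \[0, 0.5\].
#' @param color_shift Length-3 numeric, per-channel relative stain shift in
#'   \[-0.25, 0.25\], emulating inter-image staining differences.
#' @param noise_sigma Gaussian pixel noise standard deviation in 8-bit units.
#' @param seed Integer seed; fixes the generated sample bit-exactly.
#'
#' @return An object of class `panseg_spec`.
#' @seealso [generate_sample()], [generate_cohort()]
#' @export
#' @examples
#' spec <- synthetic_spec(128, 128, seed = 7)
#' sample <- generate_sample(spec)
synthetic_spec <- function(height = 256L, width = 256L,
                           target_fractions = c(acinar = 0.40, adm = 0.20,
                                                dysplasia = 0.15, other = 0.25),
                           n_lesions = 3L,
                           lumen_fraction = 0.25,
                           unevenness_amplitude = 0.15,
                           color_shift = c(0, 0, 0),
                           noise_sigma = 3,
                           seed = 1L) {
  if (height < 8 || width < 8) abort("image must be at least 8 x 8 pixels")
  need <- c("acinar", "adm", "dysplasia", "other")
  if (!all(need %in% names(target_fractions))) {
    abort("`target_fractions` must name acinar, adm, dysplasia and other")
  }
  tf <- target_fractions[need]
  if (any(tf < 0) || any(tf > 1)) abort("all target fractions must be in [0, 1]")
  if (sum(tf) > 1 + 1e-9) abort("target fractions must sum to at most 1")
  if (n_lesions == 0 && (tf[["adm"]] > 0 || tf[["dysplasia"]] > 0)) {
    abort("ductal target fractions require `n_lesions` >= 1")
  }
  assert_scalar_in(lumen_fraction, 0, 0.9, "lumen_fraction")
  assert_scalar_in(unevenness_amplitude, 0, 0.5, "unevenness_amplitude")
  if (length(color_shift) != 3 || any(abs(color_shift) > 0.25)) {
    abort("`color_shift` must be 3 values in [-0.25, 0.25]")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 target_fractions = tf, n_lesions = as.integer(n_lesions),
                 lumen_fraction = lumen_fraction,
                 unevenness_amplitude = unevenness_amplitude,
                 color_shift = as.numeric(color_shift),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "panseg_spec")
}

# Smooth standard-normal random field: coarse iid grid, bilinearly upsampled.
# `knots` controls the spatial scale (fewer knots = smoother field).
smooth_field <- function(h, w, knots = 8L) {
  k <- max(2L, as.integer(knots))
  coarse <- matrix(rnorm(k * k), k, k)
  ri <- seq(1, k, length.out = h)
  rj <- seq(1, k, length.out = w)
  i0 <- pmin(floor(ri), k - 1L); fi <- ri - i0
  j0 <- pmin(floor(rj), k - 1L); fj <- rj - j0
  a <- coarse[cbind(rep(i0, w), rep(j0, each = h))]
  b <- coarse[cbind(rep(i0 + 1, w), rep(j0, each = h))]
  cc <- coarse[cbind(rep(i0, w), rep(j0 + 1, each = h))]
  d <- coarse[cbind(rep(i0 + 1, w), rep(j0 + 1, each = h))]
  fi_r <- rep(fi, w); fj_r <- rep(fj, each = h)
  v <- a * (1 - fi_r) * (1 - fj_r) + b * fi_r * (1 - fj_r) +
    cc * (1 - fi_r) * fj_r + d * fi_r * fj_r
  f <- matrix(v, h, w)
  s <- sd(f)
  if (s > 0) f <- (f - mean(f)) / s
  f
}

# Rasterize one ring-shaped lesion: disk of radius r around (ci, cj) with a
# concentric lumen of radius rl, both boundaries modulated angularly by
# `irregularity` for the papillary look of dysplasia. Returns linear pixel
# indices of the ring and of the lumen.
rasterize_lesion <- function(h, w, ci, cj, r, lumen_fraction, irregularity) {
  rl <- r * sqrt(lumen_fraction)
  pad <- ceiling(r * (1 + irregularity)) + 1L
  i <- max(1L, floor(ci - pad)):min(h, ceiling(ci + pad))
  j <- max(1L, floor(cj - pad)):min(w, ceiling(cj + pad))
  di <- outer(i - ci, rep(1, length(j)))
  dj <- outer(rep(1, length(i)), j - cj)
  dist <- sqrt(di^2 + dj^2)
  if (irregularity > 0) {
    theta <- atan2(dj, di)
    k1 <- runif(1, 2, 4); k2 <- runif(1, 5, 7)
    p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
    mod <- 1 + irregularity * (0.6 * sin(k1 * theta + p1) + 0.4 * sin(k2 * theta + p2))
  } else {
    mod <- 1
  }
  disk <- dist <= r * mod
  lumen <- dist <= rl * mod
  lin <- outer(i, (j - 1L) * h, `+`)
  list(ring = lin[disk & !lumen], lumen = lin[lumen])
}

# Per-class base colors (R, G, B on the 8-bit scale) and texture parameters.
# Chosen to echo H&E morphology without claiming realism: acinar is a mid
# purple-pink with dense dark nuclear dots; ADM a light ductal epithelium;
# dysplasia a darker, strongly mottled epithelium; "other" a pale pink
# stroma. The green channel stays well below the 200 background threshold
# for every class so staining gradients cannot masquerade as background.
SYNTH_PALETTE <- list(
  acinar    = list(base = c(180, 120, 175), dark = c(95, 55, 100)),
  adm       = list(base = c(210, 150, 190)),
  dysplasia = list(base = c(130, 70, 140)),
  other     = list(base = c(235, 150, 205))
)
SYNTH_BACKGROUND <- c(245, 245, 245)

#' Generate one synthetic H&E-like sample with exact ground truth
#'
#' Builds an RGB image plus a pixel-exact class label map and matched
#' synthetic "immunofluorescence" channels. The cellular region is a smooth
#' blob on a white background; ductal lesions (ADM, dysplasia) are ring-like
#' structures whose lumina are left background-colored; the remaining
#' cellular area is split between acinar tissue and stroma ("other") along a
#' smooth random field so classes form spatially coherent regions. Classes
#' carry deliberately distinct color/texture statistics so that a small
#' segmentation network can learn them. Uneven staining is a smooth
#' multiplicative gradient on tissue pixels; noise is added last so the
#' ground truth is exact by construction.
#'
#' The IF channels are defined from the truth map: `if_amy` marks acinar
#' pixels (amylase), `if_pank` marks ADM and dysplasia (pan-keratin),
#' `if_dapi` marks all cellular pixels (nuclei).
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `panseg_sample`: list with `image` (H x W x 3,
#'   0-255), `truth` (H x W integer matrix, see [label_codes()]), logical
#'   matrices `if_amy`, `if_pank`, `if_dapi`, and the `spec`.
#' @export
generate_sample <- function(spec) {
  if (!inherits(spec, "panseg_spec")) abort("`spec` must be a synthetic_spec()")
  withr::with_seed(spec$seed, generate_sample_impl(spec))
}

generate_sample_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  tf <- spec$target_fractions
  s <- sum(tf)
  tfn <- if (s > 0) tf / s else tf  # renormalized over the cellular region

  # --- cellular footprint: elliptical core + smooth boundary noise,
  # thresholded at a quantile so its area is exact
  base_cellular <- 0.72 * s
  ii <- matrix(seq_len(h), h, w); jj <- matrix(rep(seq_len(w), each = h), h, w)
  ci <- h * runif(1, 0.45, 0.55); cj <- w * runif(1, 0.45, 0.55)
  eld <- sqrt(((ii - ci) / (0.62 * h))^2 + ((jj - cj) / (0.62 * w))^2)
  field <- eld + 0.25 * smooth_field(h, w, 5L)
  n_cell0 <- round(base_cellular * h * w)
  if (n_cell0 < 1) abort("target fractions leave no cellular area")
  cellular <- field <= sort(as.vector(field))[n_cell0]

  truth <- matrix(PANSEG_CODES[["background"]], h, w)

  # --- ductal lesions: solve ring/lumen areas so realized fractions of the
  # final cellular region (blob minus lumina) match the targets
  lf <- spec$lumen_fraction
  f_duct <- tfn[["adm"]] + tfn[["dysplasia"]]
  A0 <- sum(cellular)
  C_final <- A0 / (1 + lf / (1 - lf) * f_duct)
  lumen_px <- integer(0)
  centers <- matrix(numeric(0), ncol = 3) # ci, cj, r
  for (cls in c("dysplasia", "adm")) {    # place larger, irregular ones first
    f_c <- tfn[[cls]]
    if (f_c <= 0 || spec$n_lesions == 0) next
    D <- f_c * C_final / (1 - lf) / spec$n_lesions  # disk pixels per lesion
    r <- sqrt(D / pi)
    if (2 * r > min(h, w)) {
      abort(sprintf("image too small for a %s lesion of diameter %.0f px", cls, 2 * r))
    }
    irr <- if (cls == "dysplasia") 0.25 else 0.05
    cell_idx <- which(cellular & truth == PANSEG_CODES[["background"]])
    # candidate centers must keep the whole disk inside the cellular blob
    # (probed on a circle of sample points) and lesions pairwise disjoint;
    # after 300 tries the best-effort candidate is accepted, and any area
    # deficit from clipping is made up by a compensation lesion below.
    probe_ok <- function(pi0, pj0, rr) {
      ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
      pis <- pmin(h, pmax(1, round(pi0 + rr * cos(ang))))
      pjs <- pmin(w, pmax(1, round(pj0 + rr * sin(ang))))
      mean(cellular[cbind(pis, pjs)]) >= 0.95
    }
    place_one <- function(r) {
      for (try in 1:300) {
        pick <- cell_idx[sample.int(length(cell_idx), 1L)]
        pi0 <- ((pick - 1L) %% h) + 1L
        pj0 <- ((pick - 1L) %/% h) + 1L
        clear <- if (nrow(centers) == 0) TRUE else {
          all(sqrt((centers[, 1] - pi0)^2 + (centers[, 2] - pj0)^2) >=
                centers[, 3] + r + 2)
        }
        if (clear && probe_ok(pi0, pj0, r * (1 + irr))) break
      }
      les <- rasterize_lesion(h, w, pi0, pj0, r, lf, irr)
      ring <- les$ring[cellular[les$ring] & truth[les$ring] == PANSEG_CODES[["background"]]]
      lum <- les$lumen[cellular[les$lumen] & truth[les$lumen] == PANSEG_CODES[["background"]]]
      truth[ring] <<- PANSEG_CODES[[cls]]
      lumen_px <<- c(lumen_px, lum)
      centers <<- rbind(centers, c(pi0, pj0, r * (1 + irr)))
      length(ring)
    }
    got <- 0
    for (l in seq_len(spec$n_lesions)) got <- got + place_one(r)
    target_ring <- f_c * C_final
    for (extra in 1:4) {
      deficit <- target_ring - got
      if (deficit <= 0.01 * C_final) break
      r_extra <- min(r, sqrt(deficit / (1 - lf) / pi))
      if (2 * r_extra > min(h, w) || r_extra < 2) break
      got <- got + place_one(r_extra)
    }
  }
  cellular[lumen_px] <- FALSE
  truth[lumen_px] <- PANSEG_CODES[["background"]]

  # --- split the remaining cellular pixels between acinar and other along a
  # smooth field, hitting the target acinar count exactly
  rest <- which(cellular & truth == PANSEG_CODES[["background"]])
  f_ao <- tfn[["acinar"]] + tfn[["other"]]
  if (length(rest) > 0 && f_ao > 0) {
    # size the acinar share against the realized cellular area so that
    # rounding in the lesion rasterization lands in "other", not acinar
    c_real <- sum(cellular)
    n_acinar <- min(length(rest), round(tfn[["acinar"]] * c_real))
    split_f <- smooth_field(h, w, 6L)[rest]
    ord <- order(split_f)
    truth[rest[ord[seq_len(n_acinar)]]] <- PANSEG_CODES[["acinar"]]
    if (n_acinar < length(rest)) {
      truth[rest[ord[(n_acinar + 1):length(rest)]]] <- PANSEG_CODES[["other"]]
    }
  } else if (length(rest) > 0) {
    # degenerate: everything ductal; absorb leftovers into "other"
    truth[rest] <- PANSEG_CODES[["other"]]
  }

  # --- coloring
  image <- array(0, c(h, w, 3))
  for (ch in 1:3) image[, , ch][truth == 0L] <- SYNTH_BACKGROUND[ch]

  tex_fine <- smooth_field(h, w, max(4L, round(min(h, w) / 6)))
  tex_mid <- smooth_field(h, w, max(4L, round(min(h, w) / 16)))
  tex_low <- smooth_field(h, w, 5L)
  acinar_px <- truth == PANSEG_CODES[["acinar"]]
  dots <- acinar_px & (tex_fine > quantile(tex_fine, 0.70))
  for (ch in 1:3) {
    chan <- image[, , ch]
    chan[acinar_px] <- SYNTH_PALETTE$acinar$base[ch]
    chan[dots] <- SYNTH_PALETTE$acinar$dark[ch]
    adm_px <- truth == PANSEG_CODES[["adm"]]
    chan[adm_px] <- SYNTH_PALETTE$adm$base[ch] + 8 * tex_fine[adm_px]
    dys_px <- truth == PANSEG_CODES[["dysplasia"]]
    chan[dys_px] <- SYNTH_PALETTE$dysplasia$base[ch] + 20 * tex_mid[dys_px]
    oth_px <- truth == PANSEG_CODES[["other"]]
    chan[oth_px] <- SYNTH_PALETTE$other$base[ch] + 10 * tex_low[oth_px]
    image[, , ch] <- chan
  }

  # --- uneven staining: smooth multiplicative planar + radial gradient,
  # tissue pixels only (this is what crop-wise normalization corrects)
  tissue <- truth != 0L
  if (spec$unevenness_amplitude > 0) {
    ang <- runif(1, 0, 2 * pi)
    planar <- cos(ang) * (ii - h / 2) / h + sin(ang) * (jj - w / 2) / w
    radial <- sqrt(((ii - ci) / h)^2 + ((jj - cj) / w)^2)
    g <- planar + 0.5 * (radial - mean(radial))
    g <- g / max(abs(g))
    u <- 1 + spec$unevenness_amplitude * g
    for (ch in 1:3) {
      chan <- image[, , ch]
      chan[tissue] <- chan[tissue] * u[tissue]
      image[, , ch] <- chan
    }
  }

  # --- inter-image color shift (tissue only; background stays white)
  for (ch in 1:3) {
    if (spec$color_shift[ch] != 0) {
      chan <- image[, , ch]
      chan[tissue] <- chan[tissue] * (1 + spec$color_shift[ch])
      image[, , ch] <- chan
    }
  }

  # --- pixel noise last, so `truth` is exact by construction
  if (spec$noise_sigma > 0) {
    image <- image + array(rnorm(length(image), 0, spec$noise_sigma), dim(image))
  }
  image <- round(clip255(image))

  structure(list(
    image = image,
    truth = truth,
    if_amy = truth == PANSEG_CODES[["acinar"]],
    if_pank = truth == PANSEG_CODES[["adm"]] | truth == PANSEG_CODES[["dysplasia"]],
    if_dapi = truth != PANSEG_CODES[["background"]],
    spec = spec
  ), class = "panseg_sample")
}

#' Generate a cohort of synthetic samples with a composition manifest
#'
#' @param specs Non-empty list of [synthetic_spec()] objects.
#' @return List with `samples` (list of `panseg_sample`) and `manifest`, a
#'   tibble with one row per sample and class: `sample_id`, `class`,
#'   `pixel_count`, `fraction` (of the cellular region).
#' @export
generate_cohort <- function(specs) {
  if (!is.list(specs) || length(specs) == 0) {
    abort("`specs` must be a non-empty list of synthetic_spec() objects")
  }
  samples <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    samples[[i]] <- tryCatch(
      generate_sample(specs[[i]]),
      error = function(e) abort(sprintf("sample %d failed: %s", i, conditionMessage(e)))
    )
  }
  manifest <- purrr::map_dfr(seq_along(samples), function(i) {
    realized_fractions(samples[[i]]$truth, sample_id = i)
  })
  list(samples = samples, manifest = manifest)
}

# Exhaustive per-class tally of a truth/label map, as cellular fractions.
realized_fractions <- function(truth, sample_id = NA_integer_) {
  cellular <- sum(truth != PANSEG_CODES[["background"]])
  purrr::map_dfr(c("other", PANSEG_CLASSES), function(cls) {
    n <- sum(truth == PANSEG_CODES[[cls]])
    tibble(sample_id = sample_id, class = cls, pixel_count = n,
           fraction = if (cellular > 0) n / cellular else NA_real_)
  })
}

#' Synthetically perturb H&E staining
#'
#' Emulates staining variability: each channel is multiplied by an
#' independent factor drawn uniformly from `[1 - max_shift, 1 + max_shift]`,
#' then i.i.d. Gaussian noise with standard deviation `noise_sigma` is
#' added, and values are clipped to \[0, 255\].
#'
#' @param image H x W x 3 array, values 0-255.
#' @param max_shift Maximum relative channel shift, in \[0, 0.5\].
#' @param noise_sigma Gaussian noise standard deviation (8-bit units), >= 0.
#' @param seed Integer seed.
#' @return Perturbed image, same shape, values in \[0, 255\].
#' @export
perturb_stain <- function(image, max_shift = 0.25, noise_sigma = 5, seed = 1L) {
  assert_image(image)
  assert_scalar_in(max_shift, 0, 0.5, "max_shift")
  if (!is.numeric(noise_sigma) || noise_sigma < 0) abort("`noise_sigma` must be >= 0")
  withr::with_seed(seed, {
    factors <- runif(3, 1 - max_shift, 1 + max_shift)
    out <- image
    for (ch in 1:3) out[, , ch] <- out[, , ch] * factors[ch]
    if (noise_sigma > 0) {
      out <- out + array(rnorm(length(out), 0, noise_sigma), dim(out))
    }
    clip255(out)
  })
}
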