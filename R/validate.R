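# Input validation shared across modules. Images are plain base-R arrays:
# H x W x 3 numeric in [0, 255] (8-bit scale, not necessarily integer-typed).

# clip to the 8-bit range without disturbing dim attributes
clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

assert_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort(sprintf("`%s` must be an H x W x 3 array (RGB, 0-255).", arg))
  }
  if (!is.numeric(image)) abort(sprintf("`%s` must be numeric.", arg))
  rng <- range(image)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    abort(sprintf("`%s` must have values in [0, 255] with no NAs.", arg))
  }
  invisible(image)
}

assert_mask <- function(mask, image = NULL, arg = "mask") {
  if (!is.matrix(mask) || !(is.logical(mask) || all(mask %in% c(0, 1)))) {
    abort(sprintf("`%s` must be a logical (or 0/1) matrix.", arg))
  }
  if (!is.null(image) && !identical(dim(mask), dim(image)[1:2])) {
    abort(sprintf("`%s` must match the image's height and width.", arg))
  }
  invisible(mask)
}

assert_prob_map <- function(p, arg = "prob") {
  if (!is.matrix(p) || !is.numeric(p)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  rng <- range(p)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1) {
    abort(sprintf("`%s` must have values in [0, 1] with no NAs.", arg))
  }
  invisible(p)
}

assert_scalar_in <- function(x, lo, hi, arg, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    if (strict) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%g, %g%s.",
                  arg, if (strict) "(" else "[", lo, hi,
                  if (strict) ")" else "]"))
  }
  invisible(x)
}
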