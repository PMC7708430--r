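# Readers/writers for the formats the pipeline exchanges: 8-bit RGB
# TIFF/PNG images, single-channel PNG label maps (codes 0..4) and binary
# masks, CSV reports, YAML configuration.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext == "png") "png"
  else abort(sprintf("unsupported image format: '%s' (use .png or .tiff)", ext))
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", 32)
  as.integer(hdr[25]) # IHDR bit-depth byte
}

#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' Inputs with other bit depths fail unless `allow_convert = TRUE`, in
#' which case they are rescaled to 8 bits.
#'
#' @param path File path (.png, .tif, .tiff).
#' @param allow_convert Permit lossy conversion of non-8-bit inputs.
#' @return H x W x 3 array, values 0-255.
#' @export
read_image <- function(path, allow_convert = FALSE) {
  fmt <- img_format(path)
  if (fmt == "png") {
    depth <- png_bit_depth(path)
    if (depth != 8 && !allow_convert) {
      abort(sprintf("%s is %d-bit; pass allow_convert = TRUE to rescale", path, depth))
    }
    arr <- png::readPNG(path)
  } else {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample") %||% 8L
    if (bits != 8 && !allow_convert) {
      abort(sprintf("%s is %d-bit; pass allow_convert = TRUE to rescale", path, bits))
    }
  }
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE] # drop alpha
  round(arr * 255)
}

#' Write an 8-bit RGB image (PNG or TIFF)
#'
#' @param image H x W x 3 array, 0-255.
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  assert_image(image)
  fmt <- img_format(path)
  arr <- round(image) / 255
  if (fmt == "png") png::writePNG(arr, path) else tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read / write a label map as a single-channel PNG
#'
#' Label maps store the class codes of [label_codes()] directly as byte
#' values. Reading validates that only codes 0..4 occur.
#'
#' @param labels Integer label matrix.
#' @param path PNG path.
#' @return `read_label_map()`: integer matrix of class `panseg_labels`;
#'   `write_label_map()`: `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (!all(labels %in% PANSEG_CODES)) abort("labels must use codes 0..4")
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- round(png::readPNG(path) * 255)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  if (!all(m %in% PANSEG_CODES)) {
    abort(sprintf("%s contains values outside the label code table 0..4", path))
  }
  structure(matrix(as.integer(m), nrow(m), ncol(m)),
            class = c("panseg_labels", "matrix", "array"))
}

#' Read / write a binary mask as a single-channel PNG
#'
#' Masks are stored as 0/255 bytes.
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `read_mask()`: logical matrix; `write_mask()`: `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG((mask > 0) * 1.0, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Run configuration for the end-to-end pipeline
#'
#' A single validated configuration object whose defaults are the published
#' settings (Reinhard normalization on 5000 px crops with 50% overlap,
#' background threshold 200, 512 px tiles at stride 256, thresholds
#' 0.3/0.5/0.7, the published training recipe), so an empty call reproduces
#' them. Serializes losslessly to YAML.
#'
#' @param normalization Method: `"reinhard"`, `"macenko"` or `"vahadane"`.
#' @param mode `"crops"` (intermediate crops) or `"whole"` image.
#' @param crop_size,overlap Crop normalization parameters.
#' @param bg_threshold Background threshold (strict `>`).
#' @param tile_size,stride Tiling parameters.
#' @param thresholds A [class_thresholds()] or plain named list.
#' @param training A [training_config()] or plain named list.
#' @param seed Master seed for the run.
#' @param n_train,n_test,image_size Synthetic-cohort sizes used when the
#'   pipeline generates its own data.
#' @return Object of class `run_config` (a validated named list).
#' @export
run_config <- function(normalization = "reinhard", mode = "crops",
                       crop_size = 5000L, overlap = 0.5, bg_threshold = 200,
                       tile_size = 512L, stride = 256L,
                       thresholds = class_thresholds(),
                       training = training_config(),
                       seed = 1L, n_train = 10L, n_test = 5L,
                       image_size = 192L) {
  if (!normalization %in% c("reinhard", "macenko", "vahadane")) {
    abort("`normalization` must be reinhard, macenko or vahadane")
  }
  if (!mode %in% c("crops", "whole")) abort('`mode` must be "crops" or "whole"')
  if (is.list(thresholds) && !inherits(thresholds, "class_thresholds")) {
    thresholds <- do.call(class_thresholds, thresholds)
  }
  if (is.list(training) && !inherits(training, "training_config")) {
    training <- do.call(training_config, training)
  }
  assert_scalar_in(overlap, 0, 1 - 1e-9, "overlap")
  assert_scalar_in(bg_threshold, 0, 255, "bg_threshold")
  structure(list(normalization = normalization, mode = mode,
                 crop_size = as.integer(crop_size), overlap = overlap,
                 bg_threshold = bg_threshold, tile_size = as.integer(tile_size),
                 stride = as.integer(stride), thresholds = thresholds,
                 training = training, seed = as.integer(seed),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 image_size = as.integer(image_size)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()`: a validated `run_config`;
#'   `write_run_config()`: `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config()")
  plain <- unclass(config)
  plain$thresholds <- unclass(plain$thresholds)
  plain$training <- unclass(plain$training)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  plain <- yaml::read_yaml(path)
  do.call(run_config, plain)
}
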