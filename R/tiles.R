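#' Plan a deterministic overlapping tile grid
#'
#' Row-major grid of `tile_size` x `tile_size` windows at the given stride,
#' with 0-based, half-open pixel intervals. Edge tiles are anchored so their
#' far edge coincides with the image edge (real pixels only, no padding);
#' every pixel is covered by at least one tile. An image smaller than
#' `tile_size` in a dimension yields a single tile spanning that dimension
#' (with a notice).
#'
#' @param height,width Image size in pixels.
#' @param tile_size Tile edge (default 512).
#' @param stride Offset between tile starts, `1 <= stride <= tile_size`.
#' @param quiet Suppress the small-image notice.
#' @return Object of class `tile_grid`: `tiles` (tibble with `tile_id`,
#'   `row_start`, `col_start`; 0-based), `tile_h`, `tile_w`, `stride`,
#'   `image_height`, `image_width`.
#' @export
#' @examples
#' plan_grid(768, 512, tile_size = 512, stride = 256)$tiles
plan_grid <- function(height, width, tile_size = 512L, stride = 256L, quiet = FALSE) {
  if (tile_size < 1) abort("`tile_size` must be >= 1")
  if (stride < 1 || stride > tile_size) abort("`stride` must be in [1, tile_size]")
  if (height < 1 || width < 1) abort("image must be at least 1 x 1")
  if (!quiet && (height < tile_size || width < tile_size)) {
    inform("image smaller than tile_size; using a single tile over the short dimension")
  }
  tile_h <- min(tile_size, height)
  tile_w <- min(tile_size, width)
  starts <- function(extent, tile) {
    s <- seq(0L, max(0L, extent - tile), by = stride)
    if (s[length(s)] != extent - tile) s <- c(s, extent - tile)
    as.integer(s)
  }
  rs <- starts(height, tile_h)
  cs <- starts(width, tile_w)
  tiles <- tibble(
    tile_id = seq_len(length(rs) * length(cs)),
    row_start = rep(rs, each = length(cs)),
    col_start = rep(cs, times = length(rs))
  )
  structure(list(tiles = tiles, tile_h = as.integer(tile_h),
                 tile_w = as.integer(tile_w), stride = as.integer(stride),
                 image_height = as.integer(height),
                 image_width = as.integer(width)),
            class = "tile_grid")
}

#' Cut tiles from an image or map according to a grid
#'
#' @param x H x W matrix or H x W x C array.
#' @param grid A [plan_grid()] result for the same image size.
#' @return List of tiles in grid order (row-major).
#' @export
cut_tiles <- function(x, grid) {
  d <- dim(x)
  if (d[1] != grid$image_height || d[2] != grid$image_width) {
    abort("`x` does not match the grid's image size")
  }
  is_mat <- length(d) == 2L
  purrr::map(seq_len(nrow(grid$tiles)), function(k) {
    ri <- grid$tiles$row_start[k] + seq_len(grid$tile_h)
    cj <- grid$tiles$col_start[k] + seq_len(grid$tile_w)
    if (is_mat) x[ri, cj, drop = FALSE] else x[ri, cj, , drop = FALSE]
  })
}

#' Stitch per-tile predictions into a full-resolution probability map
#'
#' Each output pixel is the unweighted mean of all tile predictions covering
#' it. When every contribution to a pixel is bitwise identical the pixel is
#' set to that value directly, so cutting a map into tiles and stitching
#' them back is an exact round trip.
#'
#' @param grid A [plan_grid()] result.
#' @param tile_predictions List of `tile_h` x `tile_w` numeric matrices in
#'   \[0, 1\], one per tile, in grid order.
#' @return H x W numeric matrix in \[0, 1\].
#' @export
stitch_mean <- function(grid, tile_predictions) {
  if (!inherits(grid, "tile_grid")) abort("`grid` must be a tile_grid")
  n <- nrow(grid$tiles)
  if (length(tile_predictions) != n) {
    abort(sprintf("expected %d tile predictions, got %d", n, length(tile_predictions)))
  }
  h <- grid$image_height; w <- grid$image_width
  acc <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  first <- matrix(NA_real_, h, w)
  all_eq <- matrix(TRUE, h, w)
  for (k in seq_len(n)) {
    p <- tile_predictions[[k]]
    if (!is.matrix(p) || nrow(p) != grid$tile_h || ncol(p) != grid$tile_w) {
      abort(sprintf("tile prediction %d has the wrong shape", k))
    }
    rng <- range(p)
    if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1) {
      abort(sprintf("tile prediction %d has values outside [0, 1]", k))
    }
    ri <- grid$tiles$row_start[k] + seq_len(grid$tile_h)
    cj <- grid$tiles$col_start[k] + seq_len(grid$tile_w)
    acc[ri, cj] <- acc[ri, cj] + p
    cnt[ri, cj] <- cnt[ri, cj] + 1L
    fr <- first[ri, cj]
    fresh <- is.na(fr)
    fr[fresh] <- p[fresh]
    first[ri, cj] <- fr
    ae <- all_eq[ri, cj]
    all_eq[ri, cj] <- ae & (fr == p)
  }
  if (any(cnt == 0L)) abort("grid does not cover every pixel")
  out <- acc / cnt
  out[all_eq] <- first[all_eq]
  out
}
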