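# Binary UNet: contracting path (3x3 conv blocks + 2x2 max pool), expanding
# path (nearest-neighbor upsampling + skip concatenation + conv blocks),
# 1x1 sigmoid head. 'Same' padding throughout so the output matches the
# input spatially, which tile stitching requires. Weights live in a flat
# named list so the Adam update is a simple walk.

sigmoid <- function(z) 1 / (1 + exp(-z))

bind3 <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

upsample2 <- function(x) {
  x[rep(seq_len(dim(x)[1]), each = 2), rep(seq_len(dim(x)[2]), each = 2), , drop = FALSE]
}

downsum2 <- function(g) {
  h <- dim(g)[1]; w <- dim(g)[2]
  od <- seq(1L, h, 2L); ev <- seq(2L, h, 2L)
  oc <- seq(1L, w, 2L); ec <- seq(2L, w, 2L)
  g[od, oc, , drop = FALSE] + g[ev, oc, , drop = FALSE] +
    g[od, ec, , drop = FALSE] + g[ev, ec, , drop = FALSE]
}

#' Construct an untrained binary UNet
#'
#' @param model_scale Base channel count of the first encoder block;
#'   channels double at each depth level (full-scale default 64; the desk
#'   preset uses 8).
#' @param depth Number of pooling levels (default 4).
#' @param input_size Tile edge the network ingests; must be divisible by
#'   `2^depth`.
#' @param in_channels Input channels (3 for RGB).
#' @param seed Seed for He-normal weight initialization.
#' @return Object of class `panseg_unet` with named weight list `params`.
#' @export
build_unet <- function(model_scale = 64L, depth = 4L, input_size = 512L,
                       in_channels = 3L, seed = 1L) {
  if (input_size %% (2^depth) != 0) {
    abort(sprintf("`input_size` (%d) must be divisible by 2^depth (%d)",
                  input_size, 2^depth))
  }
  base <- as.integer(model_scale)
  new_conv <- function(cin, cout, k = 3L) {
    list(w = matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                    k * k * cin, cout),
         b = numeric(cout))
  }
  params <- withr::with_seed(seed, {
    p <- list()
    cin <- in_channels
    for (d in seq_len(depth)) {
      cout <- base * 2^(d - 1)
      p[[paste0("enc", d, "_1")]] <- new_conv(cin, cout)
      p[[paste0("enc", d, "_2")]] <- new_conv(cout, cout)
      cin <- cout
    }
    cbot <- base * 2^depth
    p[["bott_1"]] <- new_conv(cin, cbot)
    p[["bott_2"]] <- new_conv(cbot, cbot)
    for (d in rev(seq_len(depth))) {
      cskip <- base * 2^(d - 1)
      cup <- base * 2^d
      p[[paste0("dec", d, "_1")]] <- new_conv(cup + cskip, cskip)
      p[[paste0("dec", d, "_2")]] <- new_conv(cskip, cskip)
    }
    p[["out"]] <- new_conv(base, 1L, k = 1L)
    p
  })
  structure(list(params = params, depth = as.integer(depth), base = base,
                 in_channels = as.integer(in_channels),
                 input_size = as.integer(input_size)),
            class = "panseg_unet")
}

conv3_fwd <- function(params, name, x, cache) {
  p <- params[[name]]
  if (cache) {
    r <- cpp_conv3_fwd_cache(x, p$w, p$b)
  } else {
    r <- cpp_conv3_fwd(x, p$w, p$b)
  }
  z <- r$out
  a <- z * (z > 0) # ReLU
  list(out = a, z = z, cols = r$cols)
}

block_fwd <- function(params, prefix, x, cache) {
  r1 <- conv3_fwd(params, paste0(prefix, "_1"), x, cache)
  r2 <- conv3_fwd(params, paste0(prefix, "_2"), r1$out, cache)
  list(out = r2$out, c1 = r1, c2 = r2, cin = dim(x)[3])
}

block_bwd <- function(params, prefix, blk, gout, grads) {
  g2 <- gout * (blk$c2$z > 0)
  b2 <- cpp_conv3_bwd(g2, blk$c2$cols, params[[paste0(prefix, "_2")]]$w,
                      dim(blk$c1$out)[3])
  grads[[paste0(prefix, "_2")]] <- list(w = b2$dw, b = as.numeric(b2$db))
  g1 <- b2$dx * (blk$c1$z > 0)
  b1 <- cpp_conv3_bwd(g1, blk$c1$cols, params[[paste0(prefix, "_1")]]$w, blk$cin)
  grads[[paste0(prefix, "_1")]] <- list(w = b1$dw, b = as.numeric(b1$db))
  list(dx = b1$dx, grads = grads)
}

# Forward pass. x: H x W x in_channels array scaled to [0, 1].
# Returns prob (H x W matrix); with cache = TRUE also everything the
# backward pass needs.
unet_forward <- function(net, x, cache = FALSE) {
  params <- net$params
  depth <- net$depth
  skips <- vector("list", depth)
  enc_blocks <- vector("list", depth)
  pools <- vector("list", depth)
  cur <- x
  for (d in seq_len(depth)) {
    blk <- block_fwd(params, paste0("enc", d), cur, cache)
    enc_blocks[[d]] <- blk
    skips[[d]] <- blk$out
    pl <- cpp_maxpool2_fwd(blk$out)
    pools[[d]] <- pl
    cur <- pl$out
  }
  bott <- block_fwd(params, "bott", cur, cache)
  cur <- bott$out
  dec_blocks <- vector("list", depth)
  for (d in rev(seq_len(depth))) {
    up <- upsample2(cur)
    cat <- bind3(up, skips[[d]])
    blk <- block_fwd(params, paste0("dec", d), cat, cache)
    dec_blocks[[d]] <- blk
    cur <- blk$out
  }
  hw <- dim(cur)[1:2]
  z <- matrix(matrix(cur, prod(hw), dim(cur)[3]) %*% params$out$w + params$out$b,
              hw[1], hw[2])
  prob <- sigmoid(z)
  if (!cache) return(list(prob = prob))
  list(prob = prob, z = z, head_in = cur, enc_blocks = enc_blocks,
       pools = pools, bott = bott, dec_blocks = dec_blocks)
}

# Backward pass from dL/dz of the sigmoid head (H x W matrix).
# Returns the named gradient list matching net$params.
unet_backward <- function(net, fwd, dz) {
  params <- net$params
  depth <- net$depth
  grads <- list()
  hw <- dim(fwd$head_in)[1:2]
  ch <- dim(fwd$head_in)[3]
  cur_mat <- matrix(fwd$head_in, prod(hw), ch)
  gz <- as.vector(dz)
  grads[["out"]] <- list(w = crossprod(cur_mat, gz), b = sum(gz))
  gcur <- array(gz %*% t(params$out$w), c(hw, ch))
  for (d in seq_len(depth)) {
    blk <- fwd$dec_blocks[[d]]
    r <- block_bwd(params, paste0("dec", d), blk, gcur, grads)
    grads <- r$grads
    # the block input was [upsampled deeper output || skip]: split the grad
    cskip <- dim(fwd$enc_blocks[[d]]$out)[3]
    cup <- dim(r$dx)[3] - cskip
    dup <- r$dx[, , seq_len(cup), drop = FALSE]
    fwd$skip_grads[[d]] <- r$dx[, , cup + seq_len(cskip), drop = FALSE]
    # grad w.r.t. the next deeper stage's output (dec d+1, or bottleneck)
    gcur <- downsum2(dup)
  }
  r <- block_bwd(params, "bott", fwd$bott, gcur, grads)
  grads <- r$grads
  gpool <- r$dx
  for (d in rev(seq_len(depth))) {
    blk <- fwd$enc_blocks[[d]]
    gout <- cpp_maxpool2_bwd(gpool, fwd$pools[[d]]$idx,
                             dim(blk$out)[1], dim(blk$out)[2]) +
      fwd$skip_grads[[d]]
    r <- block_bwd(params, paste0("enc", d), blk, gout, grads)
    grads <- r$grads
    gpool <- r$dx
  }
  grads
}
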