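#' Training configuration
#'
#' Defaults are the published training recipe: 50 epochs, batch size 32,
#' learning rate 7e-4 with Adam, binary cross-entropy loss, 80% of the
#' relevant-tissue tiles for training (20% held out) plus ~5-10% of the
#' other-tissue tiles as negative controls (single knob `other_fraction`,
#' default 0.075), and flip/rotation/shear augmentation. Architecture
#' defaults are full scale (512 px tiles, depth 4, base 64 channels);
#' see [desk_scale_config()] for the small preset used in examples and
#' tests.
#'
#' @param epochs,batch_size,learning_rate,optimizer,loss Optimization
#'   settings; only `"adam"`/`"bce"` are implemented.
#' @param relevant_fraction Fraction of relevant tiles used for training
#'   (the rest are held out).
#' @param other_fraction Fraction of other-tissue tiles mixed in as
#'   negative controls.
#' @param augmentations Subset of `c("flip_h", "flip_v", "rotate", "shear")`.
#' @param seed Seed controlling initialization, tile sampling and
#'   augmentation.
#' @param model_scale,depth Base channel count and pooling depth of the UNet.
#' @param tile_size,stride Tile edge and tiling stride (pixels).
#' @param crop_size,overlap Intermediate normalization crop edge and
#'   fractional overlap.
#' @param selection `"bce"` (lowest held-out BCE epoch, default) or
#'   `"dice"` (highest held-out Dice).
#' @param min_class_fraction Minimum fraction of class pixels for a tile to
#'   count as "relevant" to that class.
#' @param shear_max Maximum shear angle in degrees.
#' @return Object of class `training_config`.
#' @export
training_config <- function(epochs = 50L, batch_size = 32L, learning_rate = 7e-4,
                            optimizer = "adam", loss = "bce",
                            relevant_fraction = 0.8, other_fraction = 0.075,
                            augmentations = c("flip_h", "flip_v", "rotate", "shear"),
                            seed = 1L, model_scale = 64L, depth = 4L,
                            tile_size = 512L, stride = 256L,
                            crop_size = 5000L, overlap = 0.5,
                            selection = c("bce", "dice"),
                            min_class_fraction = 0.02, shear_max = 10) {
  assert_scalar_in(relevant_fraction, 1e-9, 1, "relevant_fraction")
  assert_scalar_in(other_fraction, 0, 1, "other_fraction")
  if (learning_rate <= 0) abort("`learning_rate` must be > 0")
  if (!identical(optimizer, "adam")) abort('only optimizer = "adam" is implemented')
  if (!identical(loss, "bce")) abort('only loss = "bce" is implemented')
  bad <- setdiff(augmentations, c("flip_h", "flip_v", "rotate", "shear"))
  if (length(bad)) abort(sprintf("unknown augmentation: %s", paste(bad, collapse = ", ")))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer, loss = loss,
                 relevant_fraction = relevant_fraction, other_fraction = other_fraction,
                 augmentations = augmentations, seed = as.integer(seed),
                 model_scale = as.integer(model_scale), depth = as.integer(depth),
                 tile_size = as.integer(tile_size), stride = as.integer(stride),
                 crop_size = as.integer(crop_size), overlap = overlap,
                 selection = match.arg(selection),
                 min_class_fraction = min_class_fraction, shear_max = shear_max),
            class = "training_config")
}

#' Desk-scale training preset
#'
#' Same code paths as [training_config()] with small constants so the whole
#' pipeline (training included) runs in minutes on one CPU: 64 px tiles,
#' stride 32, 256 px normalization crops, a depth-3 UNet with 8 base
#' channels, 20 epochs of batch-4 Adam at learning rate 2e-3 (small batches
#' buy more optimizer steps per pass at this scale), flip/rotation
#' augmentation.
#'
#' @param ... Overrides passed to [training_config()].
#' @export
desk_scale_config <- function(...) {
  defaults <- list(tile_size = 64L, stride = 32L, crop_size = 256L,
                   model_scale = 8L, depth = 3L, epochs = 20L, batch_size = 4L,
                   learning_rate = 2e-3,
                   augmentations = c("flip_h", "flip_v", "rotate"))
  args <- utils::modifyList(defaults, list(...))
  do.call(training_config, args)
}

#' Binary cross-entropy loss
#'
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))` with predictions
#' clamped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param y Targets in `{0, 1}` (any numeric shape).
#' @param p Predictions in \[0, 1\], same shape as `y`.
#' @param eps Clamp constant (default 1e-7).
#' @return Non-negative scalar.
#' @export
#' @examples
#' bce_loss(c(1, 0), c(0.5, 0.5)) # log(2)
bce_loss <- function(y, p, eps = 1e-7) {
  if (length(y) != length(p)) abort("`y` and `p` must have the same length")
  if (length(y) == 0) abort("empty input")
  p <- pmin(1 - eps, pmax(eps, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Compose a per-class training set from relevant and other tiles
#'
#' Training uses `relevant_fraction` (default 80%) of the tiles relevant to
#' the class, plus `other_fraction` (default 7.5%) of other-tissue tiles as
#' negative controls; the remaining relevant tiles form the held-out set.
#' Sampling is seeded and reproducible.
#'
#' @param relevant_tiles Non-empty list (tiles relevant to the class).
#' @param other_tiles List of other-tissue tiles.
#' @param config A [training_config()].
#' @return List with `train` and `heldout` lists.
#' @export
compose_training_set <- function(relevant_tiles, other_tiles, config) {
  if (length(relevant_tiles) == 0) abort("`relevant_tiles` must be non-empty")
  withr::with_seed(config$seed, {
    n_rel <- length(relevant_tiles)
    n_train <- floor(config$relevant_fraction * n_rel)
    ord <- sample.int(n_rel)
    train_rel <- relevant_tiles[ord[seq_len(n_train)]]
    heldout <- if (n_train < n_rel) relevant_tiles[ord[(n_train + 1):n_rel]] else list()
    n_other <- floor(config$other_fraction * length(other_tiles))
    train_oth <- if (n_other > 0) {
      other_tiles[sample.int(length(other_tiles), n_other)]
    } else list()
    train <- c(train_rel, train_oth)
    list(train = train[sample.int(length(train))], heldout = heldout)
  })
}

rot90_mat <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

apply_mat_op <- function(x, f) {
  if (is.matrix(x)) return(f(x))
  out <- lapply(seq_len(dim(x)[3]), function(ch) f(x[, , ch]))
  array(unlist(out), c(dim(out[[1]]), dim(x)[3]))
}

shear_mat <- function(m, tan_a, fill) {
  h <- nrow(m); w <- ncol(m)
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(rep(seq_len(w), each = h), h, w)
  js <- round(jj + tan_a * (ii - (h + 1) / 2)) # nearest-neighbor source column
  ok <- js >= 1 & js <= w
  out <- matrix(fill, h, w)
  out[ok] <- m[cbind(ii[ok], js[ok])]
  out
}

#' Apply a random geometric augmentation to a tile and its mask
#'
#' The same transform is applied to both; masks are resampled
#' nearest-neighbor so they stay binary. `flip_h`/`flip_v` each apply with
#' probability 1/2, `rotate` draws a multiple of 90 degrees, `shear` draws
#' a horizontal shear angle in `[-shear_max, shear_max]` degrees (regions
#' sheared in from outside are filled with background).
#'
#' @param tile H x W x C array (or matrix).
#' @param mask H x W binary matrix.
#' @param ops Character subset of `c("flip_h", "flip_v", "rotate", "shear")`.
#' @param seed Integer seed.
#' @param shear_max Maximum shear angle (degrees).
#' @param fill Fill value for the tile outside the sheared frame (default 1,
#'   white on the \[0, 1\] scale).
#' @return List with transformed `tile` and `mask`.
#' @export
augment_tile <- function(tile, mask, ops = c("flip_h", "flip_v", "rotate"),
                         seed = 1L, shear_max = 10, fill = 1) {
  bad <- setdiff(ops, c("flip_h", "flip_v", "rotate", "shear"))
  if (length(bad)) abort(sprintf("unknown augmentation: %s", paste(bad, collapse = ", ")))
  dt <- if (is.matrix(tile)) dim(tile) else dim(tile)[1:2]
  if (!identical(dt, dim(mask))) abort("`tile` and `mask` must share height/width")
  withr::with_seed(seed, {
    if ("flip_h" %in% ops && runif(1) < 0.5) {
      tile <- apply_mat_op(tile, function(m) m[, rev(seq_len(ncol(m))), drop = FALSE])
      mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
    }
    if ("flip_v" %in% ops && runif(1) < 0.5) {
      tile <- apply_mat_op(tile, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
      mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
    }
    if ("rotate" %in% ops) {
      k <- sample.int(4L, 1L) - 1L
      if (k > 0 && dt[1] == dt[2]) {
        tile <- apply_mat_op(tile, function(m) rot90_mat(m, k))
        mask <- rot90_mat(mask, k)
      }
    }
    if ("shear" %in% ops) {
      tan_a <- tan(runif(1, -shear_max, shear_max) * pi / 180)
      tile <- apply_mat_op(tile, function(m) shear_mat(m, tan_a, fill))
      mask <- shear_mat(mask, tan_a, 0)
    }
    list(tile = tile, mask = mask)
  })
}

# Adam update over the flat named parameter list.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (slot in c("w", "b")) {
      g <- grads[[nm]][[slot]]
      m <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      v <- beta2 * state$v[[nm]][[slot]] + (1 - beta2) * g^2
      state$m[[nm]][[slot]] <- m
      state$v[[nm]][[slot]] <- v
      params[[nm]][[slot]] <- params[[nm]][[slot]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) list(w = p$w * 0, b = p$b * 0))
  list(m = zeros, v = zeros, t = 0L)
}

#' Train one per-class binary segmentation model
#'
#' Optimizes a binary UNet with Adam on binary cross-entropy. Each epoch
#' logs training BCE plus held-out BCE and Dice (at the standard 0.5 cut);
#' the returned weights are those of the best epoch under
#' `config$selection` (lowest held-out BCE by default, highest held-out
#' Dice on request). With no held-out tiles the final epoch is returned.
#'
#' @param train List of `list(tile = , mask = )` pairs; tiles are
#'   `tile_size` x `tile_size` x 3 arrays on the \[0, 1\] scale, masks
#'   binary matrices.
#' @param heldout Held-out list in the same format (may be empty).
#' @param config A [training_config()].
#' @param class_name One of `"acinar"`, `"adm"`, `"dysplasia"`.
#' @return Object of class `panseg_model`: `params` (selected weights),
#'   `class_name`, `config`, `input_size`, `log` (tibble: epoch,
#'   train_bce, val_bce, val_dice), `best_epoch`.
#' @export
train_model <- function(train, heldout = list(), config = training_config(),
                        class_name = "acinar") {
  if (length(train) == 0) abort("no training tiles")
  pos <- vapply(train, function(s) sum(s$mask), numeric(1))
  npx <- vapply(train, function(s) length(s$mask), numeric(1))
  if (sum(pos) == 0 || sum(pos) == sum(npx)) {
    warn("training masks are single-class; the model will learn a constant")
  }
  net <- build_unet(config$model_scale, config$depth, config$tile_size,
                    seed = config$seed)
  state <- adam_init(net$params)
  n <- length(train)
  log_rows <- vector("list", config$epochs)
  best <- list(score = Inf, params = net$params, epoch = 0L)
  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      starts <- seq(1L, n, by = config$batch_size)
      for (bs in starts) {
        idx <- ord[bs:min(bs + config$batch_size - 1L, n)]
        gacc <- NULL
        bloss <- 0
        for (i in idx) {
          s <- train[[i]]
          if (length(config$augmentations)) {
            s <- augment_tile(s$tile, s$mask, config$augmentations,
                              seed = sample.int(.Machine$integer.max, 1L),
                              shear_max = config$shear_max)
          }
          r <- cpp_unet_grad(s$tile, s$mask * 1.0, net$params, net$depth)
          bloss <- bloss + r$loss
          g <- r$grads
          gacc <- if (is.null(gacc)) g else {
            for (nm in names(g)) {
              gacc[[nm]]$w <- gacc[[nm]]$w + g[[nm]]$w
              gacc[[nm]]$b <- gacc[[nm]]$b + g[[nm]]$b
            }
            gacc
          }
        }
        nb <- length(idx)
        for (nm in names(gacc)) {
          gacc[[nm]]$w <- gacc[[nm]]$w / nb
          gacc[[nm]]$b <- gacc[[nm]]$b / nb
        }
        upd <- adam_step(net$params, gacc, state, config$learning_rate)
        net$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + bloss
      }
      train_bce <- ep_loss / n
      val <- evaluate_heldout(net, heldout)
      log_rows[[epoch]] <- tibble(epoch = epoch, train_bce = train_bce,
                                  val_bce = val$bce, val_dice = val$dice)
      score <- if (length(heldout) == 0) {
        -epoch # no held-out data: keep the last epoch
      } else if (config$selection == "bce") val$bce else -val$dice
      if (!is.na(score) && score < best$score) {
        best <- list(score = score, params = net$params, epoch = epoch)
      }
    }
  })
  structure(list(params = best$params, class_name = class_name,
                 config = config, input_size = config$tile_size,
                 depth = net$depth, base = net$base,
                 log = dplyr::bind_rows(log_rows), best_epoch = best$epoch),
            class = "panseg_model")
}

evaluate_heldout <- function(net, heldout) {
  if (length(heldout) == 0) return(list(bce = NA_real_, dice = NA_real_))
  bces <- numeric(length(heldout))
  dices <- numeric(length(heldout))
  for (i in seq_along(heldout)) {
    s <- heldout[[i]]
    p <- cpp_unet_predict(s$tile, net$params, net$depth)
    bces[i] <- bce_loss(s$mask, p)
    dices[i] <- dice(p >= 0.5, s$mask > 0)
  }
  list(bce = mean(bces), dice = mean(dices))
}

model_net <- function(model) {
  structure(list(params = model$params, depth = model$depth, base = model$base,
                 in_channels = 3L, input_size = model$input_size),
            class = "panseg_unet")
}

#' Predict a per-class probability map for a whole image
#'
#' Tiles the (already normalized) image with the model's input size,
#' predicts each tile, and stitches predictions back with overlap averaging
#' ([stitch_mean()]). Images smaller than the model input are padded with
#' white and the padding cropped off afterwards.
#'
#' @param model A [train_model()] result.
#' @param image H x W x 3 array, 0-255 (normalized like the training data).
#' @param stride Tiling stride; defaults to the training configuration's.
#' @return H x W probability matrix in \[0, 1\], with attribute
#'   `class_name`.
#' @export
predict_image <- function(model, image, stride = NULL) {
  assert_image(image)
  stride <- as.integer(stride %||% model$config$stride)
  ts <- model$input_size
  h <- dim(image)[1]; w <- dim(image)[2]
  ph <- max(h, ts); pw <- max(w, ts)
  x <- image / 255
  if (ph > h || pw > w) {
    pad <- array(1, c(ph, pw, 3))
    pad[seq_len(h), seq_len(w), ] <- x
    x <- pad
  }
  grid <- plan_grid(ph, pw, tile_size = ts, stride = min(stride, ts), quiet = TRUE)
  net <- model_net(model)
  preds <- purrr::map(cut_tiles(x, grid), function(tl) {
    cpp_unet_predict(tl, net$params, net$depth)
  })
  out <- stitch_mean(grid, preds)[seq_len(h), seq_len(w), drop = FALSE]
  attr(out, "class_name") <- model$class_name
  out
}
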