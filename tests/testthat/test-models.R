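test_that("binary cross-entropy matches closed forms and a loop oracle", {
  # clamp-perfect prediction
  expect_lt(bce_loss(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  # hand-evaluated case
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2))
  # element-wise loop oracle on random data
  withr::with_seed(3, {
    y <- rbinom(1000, 1, 0.5)
    p <- runif(1000)
    loop <- 0
    for (i in 1:1000) {
      pi <- min(1 - 1e-7, max(1e-7, p[i]))
      loop <- loop - (y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
    }
    expect_lt(abs(bce_loss(y, p) - loop / 1000), 1e-9)
  })
  expect_error(bce_loss(1, c(0.5, 0.5)), "length")
  expect_gte(bce_loss(c(1, 0), c(0.2, 0.9)), 0)
})

test_that("training-set composition follows the 80% / other-fraction rule", {
  rel <- as.list(1:100); oth <- as.list(101:200)
  cfg <- desk_scale_config(other_fraction = 0.10, seed = 5)
  sp <- compose_training_set(rel, oth, cfg)
  expect_length(sp$train, 90) # 80 relevant + 10 other
  expect_length(sp$heldout, 20)
  expect_length(intersect(unlist(sp$heldout), 101:200), 0)
  expect_identical(sort(unique(c(unlist(sp$train), unlist(sp$heldout))[
    c(unlist(sp$train), unlist(sp$heldout)) <= 100])), 1:100)

  # other_fraction = 0: purely relevant tiles
  sp0 <- compose_training_set(rel, oth, desk_scale_config(other_fraction = 0, seed = 5))
  expect_true(all(unlist(sp0$train) <= 100))

  # seeded: same seed identical, different seed same sizes different order
  sp2 <- compose_training_set(rel, oth, cfg)
  expect_identical(sp, sp2)
  sp3 <- compose_training_set(rel, oth, desk_scale_config(other_fraction = 0.10, seed = 6))
  expect_length(sp3$train, 90)
  expect_false(identical(unlist(sp$train), unlist(sp3$train)))
  expect_error(compose_training_set(list(), oth, cfg), "non-empty")
})

test_that("augmentation transforms tile and mask together", {
  tile <- array(runif(16 * 16 * 3), c(16, 16, 3))
  mask <- matrix(rbinom(256, 1, 0.3), 16, 16)
  # empty op set: identity
  a0 <- augment_tile(tile, mask, ops = character(0), seed = 1)
  expect_identical(a0$tile, tile)
  expect_identical(a0$mask, mask)
  # a flip applied twice with the same seed is the identity
  found <- FALSE
  for (sd in 1:10) {
    a1 <- augment_tile(tile, mask, ops = "flip_h", seed = sd)
    if (!identical(a1$mask, mask)) {
      found <- TRUE
      a2 <- augment_tile(a1$tile, a1$mask, ops = "flip_h", seed = sd)
      expect_identical(a2$tile, tile)
      expect_identical(a2$mask, mask)
      break
    }
  }
  expect_true(found)
  # flips and 90-degree rotations preserve the mask pixel count
  for (sd in 1:8) {
    a <- augment_tile(tile, mask, ops = c("flip_h", "flip_v", "rotate"), seed = sd)
    expect_identical(sum(a$mask), sum(mask))
    expect_identical(dim(a$tile), dim(tile))
  }
  # shears keep the mask binary
  for (sd in 1:5) {
    a <- augment_tile(tile, mask, ops = "shear", seed = sd, shear_max = 10)
    expect_true(all(a$mask %in% c(0, 1)))
  }
  expect_error(augment_tile(tile, mask, ops = "zoom"), "unknown")
})

test_that("the UNet forward pass honors its shape contract and is reproducible", {
  net <- build_unet(model_scale = 4, depth = 3, input_size = 64, seed = 2)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p <- panseg:::unet_forward(net, x)$prob
  expect_identical(dim(p), c(64L, 64L))
  expect_true(all(p > 0 & p < 1))
  # reproducible across runs
  p2 <- panseg:::unet_forward(build_unet(4, 3, 64, seed = 2), x)$prob
  expect_lt(max(abs(p - p2)), 1e-6)
  # the C++ fast path agrees with the R reference path
  pc <- panseg:::cpp_unet_predict(x, net$params, net$depth)
  expect_equal(p, pc, tolerance = 1e-12)
  expect_error(build_unet(4, 3, input_size = 60), "divisible")
})

test_that("analytic gradients match finite differences", {
  withr::with_seed(5, {
    net <- build_unet(model_scale = 3, depth = 2, input_size = 16, seed = 8)
    x <- array(runif(16 * 16 * 3), c(16, 16, 3))
    y <- matrix(rbinom(256, 1, 0.4), 16, 16)
    r <- panseg:::cpp_unet_grad(x, y * 1.0, net$params, net$depth)
    lossfn <- function(params) {
      bce_loss(y, panseg:::cpp_unet_predict(x, params, net$depth))
    }
    eps <- 1e-6
    for (nm in c("enc1_1", "enc2_2", "bott_1", "dec2_1", "dec1_2", "out")) {
      for (rep in 1:3) {
        i <- sample(length(net$params[[nm]]$w), 1)
        p2 <- net$params
        p2[[nm]]$w[i] <- p2[[nm]]$w[i] + eps
        num <- (lossfn(p2) - r$loss) / eps
        ana <- r$grads[[nm]]$w[i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
      }
    }
  })
})

test_that("training overfits a single tile and logs a decreasing loss", {
  s <- generate_sample(synthetic_spec(64, 64, seed = 7, n_lesions = 1))
  tile <- list(tile = s$image / 255, mask = (s$truth == label_codes()[["acinar"]]) * 1)
  cfg <- desk_scale_config(epochs = 200, batch_size = 1,
                           augmentations = character(0), seed = 3)
  m <- suppressWarnings(train_model(list(tile), list(), cfg, "acinar"))
  p <- predict_image(m, s$image)
  expect_gte(dice(p >= 0.5, tile$mask > 0), 0.99)
  # train loss decreases over the first 5 epochs (allow one non-monotone step)
  d5 <- diff(m$log$train_bce[1:5])
  expect_lte(sum(d5 > 0), 1)
  # config echo
  expect_identical(m$config, cfg)
  expect_identical(m$class_name, "acinar")
})

test_that("training is reproducible and warns on single-class masks", {
  s <- generate_sample(synthetic_spec(64, 64, seed = 9, n_lesions = 1))
  tile <- list(tile = s$image / 255, mask = (s$truth == label_codes()[["acinar"]]) * 1)
  held <- list(tile)
  cfg <- desk_scale_config(epochs = 3, batch_size = 1, seed = 4)
  m1 <- train_model(list(tile), held, cfg, "acinar")
  m2 <- train_model(list(tile), held, cfg, "acinar")
  expect_identical(m1$best_epoch, m2$best_epoch)
  expect_equal(m1$params, m2$params)
  expect_equal(m1$log, m2$log)
  flat <- list(tile = tile$tile, mask = tile$mask * 0)
  expect_warning(train_model(list(flat), list(), cfg, "acinar"), "single-class")
})

test_that("whole-image prediction equals a manual tile-loop-and-stitch oracle", {
  net_model <- structure(list(
    params = build_unet(4, 2, 32, seed = 6)$params,
    class_name = "acinar", depth = 2L, base = 4L, input_size = 32L,
    config = desk_scale_config(tile_size = 32L, stride = 16L, depth = 2L,
                               model_scale = 4L),
    log = tibble::tibble(), best_epoch = 0L), class = "panseg_model")
  img <- random_tissue_image(80, 56, seed = 10)
  p <- predict_image(net_model, img)
  g <- plan_grid(80, 56, tile_size = 32, stride = 16, quiet = TRUE)
  tiles <- cut_tiles(img / 255, g)
  preds <- purrr::map(tiles, function(tl) {
    panseg:::cpp_unet_predict(tl, net_model$params, 2L)
  })
  attr(p, "class_name") <- NULL
  expect_identical(p, stitch_mean(g, preds))

  # constant image gives a near-constant map away from tile borders
  const <- array(120, c(32, 32, 3))
  pc <- predict_image(net_model, const)
  expect_lt(max(pc) - min(pc), 0.05)
})
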