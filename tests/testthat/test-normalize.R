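test_that("background mask applies the strict all-channels rule", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(255, 255, 255) # background
  img[1, 2, ] <- c(201, 201, 201) # background (strictly > 200)
  img[2, 1, ] <- c(200, 255, 255) # tissue: one channel at the threshold
  img[2, 2, ] <- c(10, 10, 10)    # tissue
  bg <- background_mask(img)
  expect_identical(bg, matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  expect_identical(sum(bg), 2L)
  # per-pixel brute force
  for (i in 1:2) for (j in 1:2) {
    expect_identical(bg[i, j], all(img[i, j, ] > 200))
  }
})

test_that("reinhard statistics use tissue pixels only", {
  img <- array(0, c(4, 4, 3))
  img[, , 1] <- 120; img[, , 2] <- 60; img[, , 3] <- 140
  st <- reinhard_stats(img)
  expect_equal(unname(st$sds), c(0, 0, 0))
  # appending pure-white pixels must not move the statistics
  img2 <- random_tissue_image(8, 8, seed = 5)
  img3 <- array(255, c(8, 10, 3))
  img3[, 1:8, ] <- img2
  expect_equal(reinhard_stats(img2)$means, reinhard_stats(img3)$means)
  expect_equal(reinhard_stats(img2)$sds, reinhard_stats(img3)$sds)
  expect_error(reinhard_stats(array(255, c(4, 4, 3))), "no tissue")
})

test_that("reinhard statistics equal a direct per-pixel recomputation", {
  img <- random_tissue_image(32, 32, seed = 8)
  st <- reinhard_stats(img)
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  lab <- grDevices::convertColor(px / 255, from = "sRGB", to = "Lab")
  expect_equal(unname(st$means), unname(colMeans(lab)))
  expect_equal(unname(st$sds), unname(apply(lab, 2, sd)))
})

test_that("reinhard normalization matches reference statistics and fixes degenerates", {
  img <- random_tissue_image(32, 32, seed = 3)
  # identity: normalizing to an image's own stats returns it within round-trip error
  out <- reinhard_normalize(img, reinhard_stats(img))
  expect_lt(max(abs(out - img)), 2)
  # matching: output tissue stats equal the reference within 1% relative error
  ref <- reinhard_stats(random_tissue_image(32, 32, seed = 14))
  out2 <- reinhard_normalize(img, ref)
  st2 <- reinhard_stats(out2)
  expect_lt(max(abs(st2$means - ref$means) / pmax(abs(ref$means), 1)), 0.01)
  expect_lt(max(abs(st2$sds - ref$sds) / pmax(ref$sds, 1)), 0.01)
  # zero-variance source channel maps to the reference mean without crashing
  flat <- array(0, c(6, 6, 3))
  flat[, , 1] <- 130; flat[, , 2] <- 80; flat[, , 3] <- 150
  outf <- reinhard_normalize(flat, ref)
  stf <- reinhard_stats(outf)
  expect_lt(max(abs(stf$means - ref$means)), 1.5)
  expect_equal(unname(stf$sds), c(0, 0, 0), tolerance = 1e-6)
})

test_that("the Ruderman l-alpha-beta option round-trips", {
  img <- random_tissue_image(16, 16, seed = 6)
  st <- reinhard_stats(img, space = "lalphabeta")
  out <- reinhard_normalize(img, st)
  expect_lt(max(abs(out - img)), 2)
})

test_that("crop-wise normalization degrades to whole-image and is background-exact", {
  img <- random_tissue_image(40, 40, seed = 4)
  img[1:5, 1:5, ] <- 250 # a background patch
  ref <- reinhard_stats(random_tissue_image(40, 40, seed = 9))
  expect_message(cw <- normalize_by_crops(img, ref, crop_size = 64), "whole-image")
  wi <- reinhard_normalize(img, ref)
  expect_equal(cw, wi)
  # spatially uniform image: crop-wise equals whole-image within +-2
  cw2 <- normalize_by_crops(img, ref, crop_size = 24, overlap = 0.5, quiet = TRUE)
  expect_lt(mean(abs(cw2 - wi)), 2)
  # background pixels unchanged exactly
  bg <- background_mask(img)
  for (ch in 1:3) {
    expect_identical(cw2[, , ch][bg], img[, , ch][bg])
  }
})

test_that("crop-wise normalization flattens staining gradients better than whole-image", {
  s <- generate_sample(synthetic_spec(160, 160, seed = 31, unevenness_amplitude = 0.3))
  ref <- reinhard_stats(generate_sample(synthetic_spec(160, 160, seed = 77))$image)
  wi <- reinhard_normalize(s$image, ref)
  cw <- normalize_by_crops(s$image, ref, crop_size = 80, overlap = 0.5, quiet = TRUE)
  crop_means <- function(img) {
    g <- plan_grid(160, 160, 80, 80, quiet = TRUE)
    vapply(seq_len(nrow(g$tiles)), function(k) {
      ri <- g$tiles$row_start[k] + 1:80; cj <- g$tiles$col_start[k] + 1:80
      tissue <- s$truth[ri, cj] != 0
      mean(img[ri, cj, 1][tissue])
    }, numeric(1))
  }
  expect_lt(var(crop_means(cw)), var(crop_means(wi)))
})

test_that("normalizing twice to the same reference is nearly idempotent", {
  img <- random_tissue_image(32, 32, seed = 12)
  ref <- reinhard_stats(random_tissue_image(32, 32, seed = 13))
  once <- reinhard_normalize(img, ref)
  twice <- reinhard_normalize(once, ref)
  expect_lt(mean(abs(twice - once)), 2)
})

test_that("white balance inverts global channel gains", {
  s <- generate_sample(synthetic_spec(96, 96, seed = 19, noise_sigma = 0))
  # downward gains are exactly invertible (no clipping is involved)
  shifted <- s$image
  for (ch in 1:3) shifted[, , ch] <- shifted[, , ch] * c(0.75, 0.85, 0.95)[ch]
  expect_lt(mean(abs(white_balance(shifted) - white_balance(s$image))), 2)
  # a +-25% perturbation is inverted approximately (bright pixels clip)
  pert <- perturb_stain(s$image, max_shift = 0.25, noise_sigma = 0, seed = 3)
  expect_lt(mean(abs(white_balance(pert) - white_balance(s$image))), 6)
})
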