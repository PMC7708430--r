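test_that("a pure-acinar spec yields only acinar and background", {
  spec <- synthetic_spec(128, 128,
                         target_fractions = c(acinar = 1, adm = 0, dysplasia = 0, other = 0),
                         n_lesions = 0, seed = 4)
  s <- generate_sample(spec)
  expect_setequal(unique(as.vector(s$truth)),
                  c(label_codes()[["background"]], label_codes()[["acinar"]]))
  expect_false(any(s$if_pank))
  expect_true(any(s$if_amy))
})

test_that("identical spec and seed give byte-identical samples", {
  spec <- synthetic_spec(96, 96, seed = 11)
  expect_identical(generate_sample(spec), generate_sample(spec))
})

test_that("realized class fractions match targets, by exhaustive pixel count", {
  spec <- synthetic_spec(512, 512,
                         target_fractions = c(acinar = 0.4, adm = 0.3,
                                              dysplasia = 0.2, other = 0.1),
                         seed = 21)
  s <- generate_sample(spec)
  cellular <- sum(s$truth != 0)
  for (cls in c("acinar", "adm", "dysplasia", "other")) {
    realized <- sum(s$truth == label_codes()[[cls]]) / cellular
    expect_lt(abs(realized - spec$target_fractions[[cls]]), 0.05)
  }
})

test_that("IF channels are consistent and background is pure across seeds", {
  errs <- numeric(0)
  for (sd in 1:10) {
    spec <- synthetic_spec(128, 128, seed = sd, noise_sigma = 0)
    s <- generate_sample(spec)
    # IF-consistency, exact
    expect_false(any(s$if_amy & s$if_pank))
    expect_true(all(s$if_dapi[s$if_amy | s$if_pank]))
    expect_identical(s$if_amy, s$truth == label_codes()[["acinar"]])
    expect_identical(s$if_dapi, s$truth != 0)
    # noise-free background pixels are strictly whiter than 200 everywhere
    mins <- pmin(s$image[, , 1], pmin(s$image[, , 2], s$image[, , 3]))
    expect_true(all(mins[s$truth == 0] > 200))
    fr <- panseg:::realized_fractions(s$truth)
    errs <- c(errs, abs(setNames(fr$fraction, fr$class)[names(spec$target_fractions)] -
                          spec$target_fractions))
  }
  expect_lt(mean(errs), 0.05)
})

test_that("ductal lesions carve background lumina", {
  tf <- c(acinar = 0.3, adm = 0.25, dysplasia = 0.2, other = 0.25)
  with_lumen <- generate_sample(synthetic_spec(160, 160, target_fractions = tf,
                                               lumen_fraction = 0.3, seed = 9))
  without <- generate_sample(synthetic_spec(160, 160, target_fractions = tf,
                                            lumen_fraction = 0, seed = 9))
  expect_gt(sum(with_lumen$truth == 0), sum(without$truth == 0))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(target_fractions = c(acinar = 0.9, adm = 0.3,
                                                   dysplasia = 0, other = 0)),
               "sum")
  expect_error(synthetic_spec(n_lesions = 0), "n_lesions")
  expect_error(synthetic_spec(lumen_fraction = 2), "lumen_fraction")
  # image narrower than one lesion diameter
  expect_error(generate_sample(
    synthetic_spec(8, 80, target_fractions = c(acinar = 0.05, adm = 0,
                                               dysplasia = 0.9, other = 0.05),
                   n_lesions = 1, seed = 1)),
    "too small")
})

test_that("generate_cohort builds a manifest matching independent recounts", {
  expect_error(generate_cohort(list()), "non-empty")
  specs <- purrr::map(1:3, function(i) {
    adm <- 0.1 + 0.1 * i
    synthetic_spec(96, 96, target_fractions = c(acinar = 0.5 - adm, adm = adm,
                                                dysplasia = 0.1, other = 0.4),
                   seed = i)
  })
  cohort <- generate_cohort(specs)
  adm_fr <- cohort$manifest$fraction[cohort$manifest$class == "adm"]
  expect_true(all(diff(adm_fr) > 0))
  # manifest equals per-sample exhaustive recount
  for (i in seq_along(cohort$samples)) {
    truth <- cohort$samples[[i]]$truth
    cellular <- sum(truth != 0)
    m <- cohort$manifest[cohort$manifest$sample_id == i, ]
    for (k in seq_len(nrow(m))) {
      expect_identical(m$pixel_count[k],
                       sum(truth == label_codes()[[m$class[k]]]))
      expect_equal(m$fraction[k], m$pixel_count[k] / cellular)
    }
  }
})

test_that("perturb_stain follows its sampling model exactly", {
  img <- random_tissue_image(24, 24, seed = 2)
  # identity case
  expect_identical(perturb_stain(img, max_shift = 0, noise_sigma = 0, seed = 1), img)
  # channel means stay within +-25%
  for (sd in 1:5) {
    out <- perturb_stain(img, max_shift = 0.25, noise_sigma = 0, seed = sd)
    for (ch in 1:3) {
      ratio <- mean(out[, , ch]) / mean(img[, , ch])
      expect_gte(ratio, 0.75); expect_lte(ratio, 1.25)
    }
  }
  # closed form on a constant gray image, re-simulated independently
  gray <- array(100, c(8, 8, 3))
  out <- perturb_stain(gray, max_shift = 0.2, noise_sigma = 4, seed = 77)
  expected <- withr::with_seed(77, {
    f <- runif(3, 0.8, 1.2)
    e <- gray
    for (ch in 1:3) e[, , ch] <- e[, , ch] * f[ch]
    e <- e + array(rnorm(length(e), 0, 4), dim(e))
    e[e < 0] <- 0; e[e > 255] <- 255
    e
  })
  expect_equal(out, expected)
  expect_error(perturb_stain(img, max_shift = 0.6), "max_shift")
  expect_error(perturb_stain(img, noise_sigma = -1), "noise_sigma")
})
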