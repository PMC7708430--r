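test_that("dice handles identity, disjoint, partial and empty masks", {
  m1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_identical(dice(m1, m1), 1)
  expect_identical(dice(m1, !m1), 0)
  # |X| = 2, |Y| = 2, overlap 1 -> 0.5
  x <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  y <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  expect_equal(dice(x, y), 0.5)
  # both empty: agreement on absence
  expect_identical(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shape")
  # symmetry and range on random pairs
  withr::with_seed(2, {
    for (i in 1:200) {
      a <- matrix(rbinom(64, 1, runif(1)), 8) > 0
      b <- matrix(rbinom(64, 1, runif(1)), 8) > 0
      d <- dice(a, b)
      expect_identical(d, dice(b, a))
      expect_gte(d, 0); expect_lte(d, 1)
    }
  })
})

test_that("ssim is exactly 1 on identical images and matches the constant closed form", {
  withr::with_seed(6, {
    x <- matrix(runif(400, 0, 255), 20, 20)
    expect_identical(ssim(x, x), 1)
  })
  # two constant images: every window reduces to (2ab + C1) / (a^2 + b^2 + C1)
  a <- 120; b <- 150
  x <- matrix(a, 12, 12); y <- matrix(b, 12, 12)
  L <- b - a
  c1 <- (0.01 * L)^2
  expect_equal(ssim(x, y), (2 * a * b + c1) / (a^2 + b^2 + c1))
  # symmetry
  withr::with_seed(7, {
    x <- matrix(runif(256), 16, 16); y <- matrix(runif(256), 16, 16)
    expect_lt(abs(ssim(x, y) - ssim(y, x)), 1e-12)
  })
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "window")
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8), window = 4), "odd")
})

test_that("ssim stays within [-1, 1] and pre-blur is accepted", {
  withr::with_seed(8, {
    for (i in 1:100) {
      x <- matrix(runif(144, 0, 255), 12, 12)
      y <- matrix(runif(144, 0, 255), 12, 12)
      v <- ssim(x, y)
      expect_gte(v, -1); expect_lte(v, 1)
    }
    x <- matrix(runif(144, 0, 255), 12, 12)
    vb <- ssim(x, x, pre_blur_sigma = 1)
    expect_identical(vb, 1)
  })
})

test_that("spearman correlation equals rank-then-Pearson and flags constants", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 9, 20)), 1)
  expect_equal(spearman_cor(1:5, -(1:5)), -1)
  withr::with_seed(9, {
    for (i in 1:50) {
      x <- rnorm(6); y <- rnorm(6)
      expect_lt(abs(spearman_cor(x, y) - cor(rank(x), rank(y))), 1e-9)
    }
    # invariance under strictly monotone transforms
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(spearman_cor(x, y), spearman_cor(exp(x), y))
    expect_equal(spearman_cor(x, y), spearman_cor(x, y^3 + 2 * y))
  })
  expect_warning(v <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(v))
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

# exhaustive U and p by enumerating all label assignments (no ties)
mwu_enum <- function(a, b) {
  na <- length(a); nb <- length(b)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  vals <- c(a, b)
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(ix) {
    sum(outer(vals[ix], vals[-ix], ">")) + 0.5 * sum(outer(vals[ix], vals[-ix], "=="))
  })
  mu <- na * nb / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p = p)
}

test_that("mann-whitney U matches enumeration, symmetry and invariances", {
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$u, 4.5) # n_a * n_b / 2 with ties
  r2 <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r2$u, 9) # complete separation
  withr::with_seed(10, {
    for (i in 1:20) {
      a <- rnorm(4); b <- rnorm(4)
      r <- mann_whitney_u(a, b)
      e <- mwu_enum(a, b)
      expect_identical(r$u, e$u)
      expect_equal(r$p_value, e$p, tolerance = 1e-12)
      expect_identical(r$method, "exact")
      # shift invariance and the U_a + U_b identity
      r_shift <- mann_whitney_u(a + 5, b + 5)
      expect_identical(r_shift$u, r$u)
      expect_equal(r$u + mann_whitney_u(b, a)$u, length(a) * length(b))
    }
  })
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("mann-whitney agrees with the standard implementation", {
  withr::with_seed(11, {
    # exact regime (no ties, small groups)
    a <- rnorm(6); b <- rnorm(8)
    r <- mann_whitney_u(a, b)
    w <- wilcox.test(a, b, exact = TRUE, correct = TRUE)
    expect_equal(r$u, unname(w$statistic))
    expect_equal(r$p_value, w$p.value, tolerance = 1e-12)
    # approximate regime (large groups): wilcox.test with the same mode
    a2 <- rnorm(30); b2 <- rnorm(25)
    r2 <- mann_whitney_u(a2, b2)
    w2 <- wilcox.test(a2, b2, exact = FALSE, correct = TRUE)
    expect_identical(r2$method, "normal approximation")
    expect_equal(r2$u, unname(w2$statistic))
    expect_equal(r2$p_value, w2$p.value, tolerance = 1e-6)
    # tie handling matches too
    a3 <- c(1, 2, 2, 3, 5, 5, 6); b3 <- c(2, 3, 3, 4, 5, 7)
    r3 <- mann_whitney_u(a3, b3)
    w3 <- suppressWarnings(wilcox.test(a3, b3, exact = FALSE, correct = TRUE))
    expect_equal(r3$u, unname(w3$statistic))
    expect_equal(r3$p_value, w3$p.value, tolerance = 1e-6)
  })
})

test_that("evaluate_cohort reports per-channel correlations and mask SSIM", {
  withr::with_seed(13, {
    n <- 10
    amy <- runif(n, 0.2, 0.6); pank <- runif(n, 0.1, 0.4)
    cohort <- tibble::tibble(
      sample_id = 1:n,
      amy_pred = amy, pank_pred = pank, other_pred = 1 - amy - pank,
      amy_ref = amy, pank_ref = pank, other_ref = 1 - amy - pank)
    r <- evaluate_cohort(cohort)
    expect_equal(r$correlations$spearman, rep(1, 3))
    # permuted references lower the correlation
    cohort2 <- cohort
    cohort2$amy_ref <- cohort$pank_ref
    cohort2$pank_ref <- cohort$amy_ref
    r2 <- evaluate_cohort(cohort2)
    expect_lt(r2$correlations$spearman[r2$correlations$channel == "amy"], 1)
    # identical masks give SSIM exactly 1
    masks <- purrr::map(1:n, function(i) matrix(rbinom(100, 1, 0.4), 10) > 0)
    r3 <- evaluate_cohort(cohort, pred_masks = list(amy = masks),
                          ref_masks = list(amy = masks))
    expect_true(all(r3$ssim$ssim == 1))
    expect_error(evaluate_cohort(cohort[1:2, ]), "at least 3")
  })
})
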