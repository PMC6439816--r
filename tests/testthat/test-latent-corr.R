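test_that("standardize_by_sex centres and scales within strata", {
  expect_equal(standardize_by_sex(c(1, 2, 3), rep("M", 3)), c(-1, 0, 1))
  x <- c(1, 2, 3, 10, 20, 30, NA)
  sx <- c("M", "M", "M", "F", "F", "F", "M")
  z <- standardize_by_sex(x, sx)
  expect_equal(z[1:3], (x[1:3] - 2) / 1)
  expect_equal(z[4:6], (x[4:6] - 20) / 10)
  expect_true(is.na(z[7]))
  # idempotent
  expect_equal(standardize_by_sex(z, sx), z, tolerance = 1e-12)
  # equals concatenation of per-stratum z-scores
  expect_equal(z[!is.na(z)],
               c(scale(x[1:3])[, 1], scale(x[4:6])[, 1]))
  expect_error(standardize_by_sex(c(1, 1, 1), rep("M", 3)), "constant")
})

test_that("thresholds invert the sex-specific prevalences", {
  # printed prevalences: 0.9% -> 2.366, 3.0% -> 1.881, 50% -> 0
  expect_equal(unname(estimate_thresholds(c(rep(1, 9), rep(0, 991)),
                                          rep("M", 1000))["M"]),
               2.365618, tolerance = 1e-4)
  expect_equal(unname(estimate_thresholds(c(rep(1, 30), rep(0, 970)),
                                          rep("F", 1000))["F"]),
               1.880794, tolerance = 1e-4)
  expect_equal(unname(estimate_thresholds(rep(0:1, 50), rep("M", 100))["M"]), 0)
  # a sex with zero cases hits the boundary
  y <- c(rep(1, 5), rep(0, 95), rep(0, 100))
  sx <- c(rep("M", 100), rep("F", 100))
  th <- estimate_thresholds(y, sx)
  expect_equal(unname(th["F"]), Inf)
  expect_true(attr(th, "boundary")["F"])
  expect_error(estimate_thresholds(c(NA, NA), c("M", "F")), "missing")
})

test_that("tetrachoric correlation inverts the quadrant probability", {
  expect_equal(tetrachoric_corr(matrix(25, 2, 2))$rho, 0, tolerance = 1e-6)
  # expected counts for rho = 0.5, thresholds 0, n = 1200
  tab <- matrix(c(400, 200, 200, 400), 2, 2)
  expect_equal(tetrachoric_corr(tab)$rho, 0.5, tolerance = 1e-3)
  # a spread of generating correlations, inverted from exact expected counts
  for (rho in c(-0.6, 0.2, 0.8)) {
    p11 <- pbvn(0, 0, rho)
    p10 <- pnorm(0) - p11
    tab <- 4000 * matrix(c(p11, p10, p10, 1 - p11 - 2 * p10), 2, 2)[2:1, 2:1]
    expect_equal(tetrachoric_corr(tab)$rho, rho, tolerance = 1e-3)
  }
  # perfect concordance hits the boundary with a warning
  expect_warning(b <- tetrachoric_corr(matrix(c(50, 0, 0, 50), 2, 2)), "boundary")
  expect_equal(b$rho, 1)
  expect_warning(z <- tetrachoric_corr(matrix(c(100, 0, 10, 0), 2, 2)), "margin")
  expect_true(is.na(z$rho))
})

test_that("polyserial correlation recovers the latent correlation", {
  set.seed(401)
  # independence
  x <- rnorm(20000); y <- rbinom(20000, 1, 0.2)
  expect_lt(abs(polyserial_corr(x, y)$rho), 3 / sqrt(20000))
  # latent rho 0.6 at tau 1
  n <- 50000
  z <- rnorm(n); liab <- 0.6 * z + sqrt(1 - 0.36) * rnorm(n)
  ps <- polyserial_corr(z, as.integer(liab > 1))
  expect_lt(abs(ps$rho - 0.6), 0.02)
  # deterministic dichotomisation of x itself drives rho to the boundary
  pb <- polyserial_corr(z, as.integer(z > 0))
  expect_gt(pb$rho, 0.99)
  expect_error(polyserial_corr(z, rep(0L, n)), "constant")
})
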