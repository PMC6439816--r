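test_that("implied moments reproduce the classical twin identities", {
  # AE: cross-twin trait correlation a2 for MZ, a2/2 for DZ
  sp <- twin_spec(a2 = c(0.74, 0.5), rA = 0, rE = 0)
  expect_equal(implied_moments(sp, "MZ")[1, 3], 0.74)
  expect_equal(implied_moments(sp, "DZ")[1, 3], 0.37)
  # perfect shared genetics: cross-twin cross-trait correlation 1
  sp2 <- twin_spec(a2 = c(1 - 1e-12, 1 - 1e-12), rA = 1)
  expect_equal(implied_moments(sp2, "MZ")[1, 4], 1, tolerance = 1e-9)
  # s = 0 keeps unit diagonal
  expect_equal(diag(implied_moments(twin_spec(a2 = c(0.3, 0.6), rA = 0.5,
                                              rE = 0.2), "DZ")),
               rep(1, 4), ignore_attr = TRUE)
})

test_that("sibling interaction follows the reciprocal-path algebra", {
  # all latent variance nonshared, s = 0.2:
  # var = (1+s^2)/(1-s^2)^2, cov = 2s/(1-s^2)^2, corr = 2s/(1+s^2)
  s <- 0.2
  sp <- twin_spec(a2 = c(1e-12, 1e-12), s = c(s, 0), rE = 0)
  m <- implied_moments(sp, "MZ")
  expect_equal(m[1, 1], (1 + s^2) / (1 - s^2)^2, tolerance = 1e-9)
  expect_equal(m[1, 3], 2 * s / (1 - s^2)^2, tolerance = 1e-9)
  expect_equal(cov2cor(m)[1, 3], 2 * s / (1 + s^2), tolerance = 1e-9)
  # the untouched liability block stays standardised
  expect_equal(m[2, 2], 1, tolerance = 1e-9)
})

test_that("simulated prevalence matches the threshold and seeds reproduce", {
  # ASD-like prevalence 0.9% -> threshold qnorm(0.991) = 2.366
  expect_equal(qnorm(1 - 0.009), 2.365618, tolerance = 1e-6)
  sp <- asd_spec(n_mz = 50000, n_dz = 50000, seed = 99)
  pt <- simulate_twin_pairs(sp)
  n <- sum(!is.na(pt$diagnosis))
  prev <- mean(pt$diagnosis, na.rm = TRUE)
  mc_se <- sqrt(0.009 * 0.991 / n)
  expect_lt(abs(prev - 0.009), 3 * mc_se)
  pt2 <- simulate_twin_pairs(sp)
  expect_identical(as.data.frame(pt), as.data.frame(pt2))
  # empty spec gives an empty table, no error
  empty <- simulate_twin_pairs(twin_spec(n_pairs = c(MZM = 0)))
  expect_equal(nrow(empty), 0L)
})

test_that("MZ concordance cell matches the bivariate-normal quadrant closed form", {
  # liability correlation 0.5, thresholds 0:
  # P(both affected) = 1/4 + asin(.5)/(2pi) = 1/3
  sp <- twin_spec(a2 = c(0.5, 0.5), rA = 0, tau = c(M = 0, F = 0),
                  n_pairs = c(MZM = 60000), seed = 7)
  pt <- simulate_twin_pairs(sp)
  w <- pt$diagnosis[c(TRUE, FALSE)] & pt$diagnosis[c(FALSE, TRUE)]
  p11 <- mean(w)
  expected <- 1 / 4 + asin(0.5) / (2 * pi)
  expect_lt(abs(p11 - expected), 3 * sqrt(expected * (1 - expected) / 60000))
})

test_that("empirical moments of simulated pairs converge to implied_moments", {
  sp <- twin_spec(a2 = c(0.6, 0.7), rA = 0.5, rE = 0.3,
                  tau = c(M = 1, F = 1.2),
                  n_pairs = c(MZM = 25000, MZF = 25000), seed = 13)
  pt <- simulate_twin_pairs(sp)
  R <- cov2cor(implied_moments(sp, "MZ"))
  w <- cbind(t1 = pt$trait[c(TRUE, FALSE)], t2 = pt$trait[c(FALSE, TRUE)])
  n <- nrow(w)
  se <- 1 / sqrt(n - 3)  # Fisher-z scale
  expect_lt(abs(atanh(cor(w[, 1], w[, 2])) - atanh(R[1, 3])), 3 * se)
  # latent trait-liability correlation recovered through the polyserial
  ps <- polyserial_corr(pt$trait, pt$diagnosis)
  expect_lt(abs(ps$rho - R[1, 2]), 0.03)
})

test_that("dichotomisation commutes: tetrachoric recovers the liability correlation", {
  sp <- twin_spec(a2 = c(0.5, 0.8), rA = 0, rE = 0,
                  tau = c(M = qnorm(0.9), F = qnorm(0.9)),
                  n_pairs = c(MZM = 50000, MZF = 50000), seed = 21)
  pt <- simulate_twin_pairs(sp)
  y1 <- pt$diagnosis[c(TRUE, FALSE)]; y2 <- pt$diagnosis[c(FALSE, TRUE)]
  tab <- table(factor(y1, 0:1), factor(y2, 0:1))
  tc <- tetrachoric_corr(tab)
  expect_lt(abs(tc$rho - 0.8), 0.03)  # generating MZ liability correlation a2_l
})
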