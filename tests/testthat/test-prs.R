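toy_geno <- function() {
  variants <- data.frame(id = paste0("v", 1:5), chrom = 1L,
                         pos = c(100L, 200L, 300L, 400L, 500L),
                         allele1 = c("A", "G", "A", "C", "A"),
                         allele2 = c("G", "A", "T", "T", "C"))
  dosage <- matrix(c(2, 1, 0, 0,
                     1, 1, 2, 0,
                     0, 2, 1, 1,
                     2, 0, 1, 2,
                     1, 1, 1, 0), nrow = 4)
  genotype_data(paste0("i", 1:4), variants, dosage)
}

test_that("allele harmonisation flips, drops ambiguous, logs counts", {
  g <- toy_geno()
  ss <- gwas_sumstats(data.frame(
    id = c("v1", "v2", "v3", "v4", "v9"), chrom = 1L,
    pos = c(100L, 200L, 300L, 400L, 900L),
    effect_allele = c("A", "A", "A", "G", "A"),
    other_allele = c("G", "G", "T", "C", "G"),
    beta = c(0.1, 0.2, 0.3, 0.4, 0.5), se = 0.05, p = 0.01, n = 1000L))
  expect_message(w <- harmonize_alleles(ss, g), "flipped=1")
  # v1 straight; v2 effect allele is target allele2 -> sign flip;
  # v3 is A/T ambiguous -> dropped; v4 G/C mismatch+ambiguous -> dropped;
  # v9 absent
  expect_equal(w$id, c("v1", "v2"))
  expect_equal(w$beta, c(0.1, -0.2))
  cnt <- attr(w, "counts")
  expect_equal(unname(cnt[c("matched", "flipped", "ambiguous", "absent")]),
               c(2L, 1L, 2L, 1L))
  expect_error(harmonize_alleles(ss[5, ], g), "overlap")
})

test_that("greedy clumping keeps the documented index set and is order-invariant", {
  # A(p=1e-8), B(p=1e-4, r2(A,B) ~ 0.5), C(p=1e-3, r2(A,C) ~ 0): keep {A, C}
  set.seed(9)
  n <- 4000
  a <- rbinom(n, 2, 0.4)
  noise <- rbinom(n, 2, 0.4)
  b <- ifelse(runif(n) < 0.72, a, noise)          # r2 ~ 0.5 with a
  cc <- rbinom(n, 2, 0.4)
  variants <- data.frame(id = c("A", "B", "C"), chrom = 1L,
                         pos = c(1000L, 2000L, 3000L),
                         allele1 = "A", allele2 = "G")
  g <- genotype_data(paste0("i", 1:n), variants, cbind(a, b, cc))
  w <- data.frame(id = c("A", "B", "C"), col = 1:3, chrom = 1L,
                  pos = c(1000L, 2000L, 3000L),
                  beta = c(0.5, 0.3, 0.2), p = c(1e-8, 1e-4, 1e-3))
  kept <- ld_clump(w, g, clump_r2 = 0.1, clump_kb = 250)
  expect_equal(sort(kept$id), c("A", "C"))
  # row order does not matter
  kept2 <- ld_clump(w[c(3, 1, 2), ], g, clump_r2 = 0.1, clump_kb = 250)
  expect_equal(kept$id, kept2$id)
  # independent variants are all retained
  w_ind <- w; w_ind$col <- c(1, 3, 3)
  expect_equal(nrow(ld_clump(w_ind[c(1, 2), ], g, 0.1, 250)), 2L)
  # equal p in LD: lower position wins
  w_tie <- data.frame(id = c("B", "A"), col = c(2, 1), chrom = 1L,
                      pos = c(2000L, 1000L), beta = 0.1, p = 1e-4)
  kept3 <- ld_clump(w_tie, g, clump_r2 = 0.1, clump_kb = 250)
  expect_equal(kept3$id, "A")
})

test_that("scoring weights dosages, imputes missing, and standardises", {
  variants <- data.frame(id = c("w1", "w2"), chrom = 1L, pos = c(100L, 200L),
                         allele1 = "A", allele2 = "G")
  g <- genotype_data(c("i1", "i2", "i3"),
                     variants, matrix(c(2, 1, 0, 1, 1, 1), nrow = 3))
  w <- data.frame(id = c("w1", "w2"), col = 1:2, chrom = 1L,
                  pos = c(100L, 200L), beta = c(0.1, -0.2), p = c(0.01, 0.01))
  prof <- score_prs(g, w, thresholds = 0.5)
  expect_equal(prof$raw_0.5[1], 0.1 * 2 - 0.2 * 1)  # betas {0.1,-0.2}, dosages {2,1}
  # raw scores {0, 0.1, -0.2}... standardisation uses n-1
  expect_equal(mean(prof$z_0.5), 0, tolerance = 1e-12)
  expect_equal(sd(prof$z_0.5), 1, tolerance = 1e-12)
  expect_equal(prof$z_0.5, (prof$raw_0.5 - mean(prof$raw_0.5)) / sd(prof$raw_0.5))
  # z of {0,1,2} with n-1 denominator is {-1,0,1}
  g1 <- genotype_data(c("i1", "i2", "i3"),
                      variants[1, ], matrix(c(0, 1, 2), nrow = 3))
  w1 <- w[1, ]
  expect_equal(score_prs(g1, w1, 0.5)$z_0.5, c(-1, 0, 1))
  # missing dosage contributes beta * 2 * effect-allele frequency
  gm <- genotype_data(c("i1", "i2", "i3", "i4"), variants[1, ],
                      matrix(c(1, 0, 0, NA), nrow = 4))
  pm <- score_prs(gm, w1, 0.5)
  expect_equal(pm$raw_0.5[4], 0.1 * 2 * 0.25 / 1.5)  # freq (1)/(2*3)=1/6 -> 2f=1/3
  # score linearity before standardisation
  w2 <- w; w2$beta <- c(0.3, 0.05)
  wsum <- w; wsum$beta <- w$beta + w2$beta
  expect_equal(score_prs(g, wsum, 0.5)$raw_0.5,
               score_prs(g, w, 0.5)$raw_0.5 + score_prs(g, w2, 0.5)$raw_0.5)
  # a threshold with zero variants yields flagged zeros
  expect_warning(p0 <- score_prs(g, w, thresholds = 1e-6), "0 variants")
  expect_true(all(p0$z_1em06 == 0))
})

test_that("cluster sandwich equals HC0 with singleton clusters and the 2x2 OR", {
  skip_if_not_installed("sandwich")
  set.seed(21)
  n <- 300
  x <- rnorm(n); y <- 0.2 * x + rnorm(n)
  r <- gee_associate(y, x, NULL, clusters = seq_len(n), family = "linear")
  fit <- glm(y ~ x)
  expect_equal(r$se, sqrt(sandwich::vcovHC(fit, type = "HC0")["x", "x"]),
               tolerance = 1e-10)
  expect_equal(r$beta, unname(coef(fit)["x"]), tolerance = 1e-10)
  # clustered case against the reference implementation
  cl <- rep(1:(n / 2), each = 2)
  y2 <- y + rep(rnorm(n / 2), each = 2)
  r2 <- gee_associate(y2, x, NULL, clusters = cl, family = "linear")
  expect_equal(r2$se,
               sqrt(sandwich::vcovCL(glm(y2 ~ x), cluster = cl, type = "HC0",
                                     cadjust = FALSE)["x", "x"]),
               tolerance = 1e-10)
  # logistic toy cells a=10 b=90 c=20 d=80: OR = (10*80)/(90*20)
  yy <- c(rep(1, 10), rep(0, 90), rep(1, 20), rep(0, 80))
  xx <- c(rep(1, 100), rep(0, 100))
  r3 <- gee_associate(yy, xx, NULL, clusters = seq_along(yy),
                      family = "logistic")
  expect_equal(r3$OR, (10 * 80) / (90 * 20), tolerance = 1e-6)
  # duplicating every row within its cluster changes neither beta nor SE
  idx <- rep(seq_len(n), 2)
  r4 <- gee_associate(y2[idx], x[idx], NULL, clusters = cl[idx],
                      family = "linear")
  expect_equal(r4$beta, r2$beta, tolerance = 1e-9)
  expect_equal(r4$se, r2$se, tolerance = 1e-9)
})

test_that("diagnosed-exclusion removes individuals, not pairs, and attenuates case-driven effects", {
  d <- data.frame(id = 1:100, dx = c(rep(1L, 7), rep(0L, 93)))
  expect_message(out <- exclude_diagnosed(d, "dx"), "removed 7")
  expect_equal(nrow(out), 93L)
  expect_identical(suppressMessages(exclude_diagnosed(d[8:100, ], "dx"))$id,
                   d$id[8:100])
  # effect driven purely by cases vanishes after exclusion
  set.seed(5)
  n <- 2000
  prs <- rnorm(n)
  dx <- as.integer(prs + rnorm(n) > 2)
  y <- rnorm(n) + 2 * dx           # outcome moved only through diagnosis
  full <- gee_associate(y, prs, NULL, seq_len(n), "linear")
  d2 <- data.frame(y = y, prs = prs, dx = dx, id = seq_len(n))
  ex <- suppressMessages(exclude_diagnosed(d2, "dx"))
  red <- gee_associate(ex$y, ex$prs, NULL, ex$id, "linear")
  expect_lt(abs(red$beta), abs(full$beta))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_equal(fdr_adjust(0.3), 0.3)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  # monotone non-decreasing in rank, capped at 1
  p <- runif(50)
  adj <- fdr_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj <= 1))
})
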