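make_pairs <- function(n_mz, n_dz, seed = 1) {
  sp <- twin_spec(a2 = c(0.5, 0.5), rA = 0.3, rE = 0.2,
                  n_pairs = c(MZM = n_mz, DZM = n_dz), seed = seed)
  simulate_twin_pairs(sp)
}

test_that("MZ co-twins get identical genotypes; DZ dosage correlation ~ 0.5", {
  pt <- make_pairs(300, 1200, seed = 5)
  ps <- polygenic_spec(m_variants = 120, n_causal = 20, block_size = 6,
                       block_r = 0.3, seed = 9)
  g <- simulate_genotypes(ps, pt)
  i1 <- seq(1, length(g$ids), 2); i2 <- i1 + 1
  mz <- grepl("^MZ", g$ids[i1])
  expect_true(all(g$dosage[i1[mz], ] == g$dosage[i2[mz], ]))
  rs <- vapply(seq_len(ncol(g$dosage)), function(j)
    suppressWarnings(cor(g$dosage[i1[!mz], j], g$dosage[i2[!mz], j])), 0)
  # variants within a block share transmission events, so the effective
  # number of independent correlations is the number of blocks
  n_blocks <- ncol(g$dosage) / 6
  expect_lt(abs(mean(rs, na.rm = TRUE) - 0.5),
            3 * sd(rs, na.rm = TRUE) / sqrt(n_blocks))
})

test_that("block correlation controls within-block LD", {
  pt <- make_pairs(0, 1500, seed = 6)
  ps0 <- polygenic_spec(m_variants = 40, n_causal = 0, block_size = 4,
                        block_r = 0, seed = 2)
  g0 <- simulate_genotypes(ps0, pt)
  cm <- cor(g0$dosage)
  within <- abs(cm[1, 2:4])  # same block under block_size 4
  expect_true(all(within < 3 / sqrt(nrow(g0$dosage))))
  ps1 <- polygenic_spec(m_variants = 40, n_causal = 0, block_size = 4,
                        block_r = 0.7, seed = 2)
  g1 <- simulate_genotypes(ps1, pt)
  cm1 <- cor(g1$dosage)
  expect_gt(mean(abs(cm1[1, 2:4])), 0.25)   # strong LD inside the block
  expect_lt(mean(abs(cm1[1, 5:8])), 0.1)    # none across blocks
})

test_that("discovery summary statistics have the stated SE and null p-values", {
  # SE closed form at maf 0.5, n 50 000
  expect_equal(sqrt(1 / (2 * 0.5 * 0.5 * 50000)), 0.006324555, tolerance = 1e-6)
  pt <- make_pairs(50, 50, seed = 3)
  ps <- polygenic_spec(m_variants = 400, n_causal = 40, maf_range = c(0.5, 0.5),
                       effect_sd = 0.05, n_discovery = 50000, seed = 10)
  g <- simulate_genotypes(ps, pt)
  truth <- attr(g, "truth")
  ss <- simulate_discovery_sumstats(ps, truth)
  expect_equal(unique(ss$se), 0.006324555, tolerance = 1e-6)
  # consistency: with a huge discovery sample the estimate pins the truth
  ps_big <- polygenic_spec(m_variants = 400, n_causal = 40,
                           maf_range = c(0.5, 0.5), effect_sd = 0.05,
                           n_discovery = 5e8, seed = 10)
  ss_big <- simulate_discovery_sumstats(ps_big, truth)
  se_big <- sqrt(1 / (2 * 0.25 * 5e8))
  expect_lt(max(abs(ss_big$beta - truth$beta_true)), 4 * se_big)
  # null variants: p uniform (KS test should not reject at alpha 0.01)
  pnull <- ss$p[truth$beta_true == 0]
  expect_gt(suppressWarnings(ks.test(pnull, "punif"))$p.value, 0.01)
  # determinism
  expect_identical(simulate_discovery_sumstats(ps, truth)$beta, ss$beta)
})

test_that("attached outcomes carry the requested score heritability", {
  pt <- make_pairs(0, 5000, seed = 8)
  ps <- polygenic_spec(m_variants = 200, n_causal = 50, h2_score = 0.25,
                       effect_sd = 0.1, seed = 12)
  g <- simulate_genotypes(ps, pt)
  ph <- attach_genetic_phenotype(g, attr(g, "truth"), ps)
  r2 <- cor(ph$score_true, ph$outcome)^2
  expect_lt(abs(r2 - 0.25), 0.03)
  # zero heritability: independence up to MC noise
  ps0 <- polygenic_spec(m_variants = 200, n_causal = 50, h2_score = 0,
                        effect_sd = 0.1, seed = 12)
  ph0 <- attach_genetic_phenotype(g, attr(g, "truth"), ps0)
  expect_lt(abs(cor(ph0$score_true, ph0$outcome)), 3 / sqrt(nrow(ph0)))
})
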