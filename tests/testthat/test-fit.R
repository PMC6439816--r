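test_that("AE parameters are recovered from AE data", {
  sp <- twin_spec(a2 = c(0.6, 0.7), rA = 0.5, rE = 0.3,
                  tau = c(M = 1, F = 1.2),
                  n_pairs = c(MZM = 4000, MZF = 4000, DZM = 3000, DZF = 3000,
                              DZOS = 2000), seed = 31)
  pt <- simulate_twin_pairs(sp)
  f <- fit_structural(pt, "trait", "diagnosis", family = "AE",
                      restarts = 1, seed = 4)
  est <- coef(f)
  expect_lt(abs(est[["a2.trait"]] - 0.6), 0.04)
  expect_lt(abs(est[["a2.liab"]] - 0.7), 0.08)
  expect_lt(abs(est[["rA"]] - 0.5), 0.06)
  expect_lt(abs(est[["rE"]] - 0.3), 0.06)
  expect_lt(abs(est[["tau.M"]] - 1), 0.05)
  expect_lt(abs(est[["tau.F"]] - 1.2), 0.05)
  # BIC identity holds exactly
  expect_equal(f$BIC, -2 * f$loglik + f$npar * log(f$N), tolerance = 1e-10)
  expect_equal(f$npar, 6L)
  # derived decomposition shares sum to one over active components
  expect_equal(sum(f$derived$shares[c("A", "E")]), 1, tolerance = 1e-8)
})

test_that("ACE parameters are recovered to the stated precision", {
  errs <- c()
  for (rep in 1:3) {
    sp <- twin_spec(a2 = c(0.45, 0.5), c2 = c(0.2, 0.15), rA = 0.5,
                    rC = 0.3, rE = 0.25, tau = c(M = qnorm(0.7), F = qnorm(0.7)),
                    n_pairs = c(MZM = 5000, MZF = 5000, DZM = 5000, DZF = 5000),
                    seed = 300 + rep)
    pt <- simulate_twin_pairs(sp)
    f <- fit_structural(pt, "trait", "diagnosis", family = "ACE",
                        restarts = 1, seed = rep)
    tgt <- c(a2.trait = 0.45, a2.liab = 0.5, c2.trait = 0.2, c2.liab = 0.15,
             rA = 0.5, rC = 0.3, rE = 0.25)
    errs <- rbind(errs, abs(coef(f)[names(tgt)] - tgt))
  }
  med <- apply(errs, 2, median)
  expect_true(all(med < 0.05), info = paste(round(med, 3), collapse = " "))
})

test_that("ADE fits recover the identifiable genetic summaries", {
  # the A/D split within one phenotype is weakly identified at realistic
  # sample sizes; total genetic variance and the implied moments are the
  # stable summaries and must come back accurately
  sp <- twin_spec(a2 = c(0.45, 0.5), d2 = c(0.2, 0.15), rA = 0.5,
                  rD = 0.3, rE = 0.25, tau = c(M = qnorm(0.7), F = qnorm(0.7)),
                  n_pairs = c(MZM = 5000, MZF = 5000, DZM = 5000, DZF = 5000),
                  seed = 555)
  pt <- simulate_twin_pairs(sp)
  f <- fit_structural(pt, "trait", "diagnosis", family = "ADE",
                      restarts = 1, seed = 3)
  est <- coef(f)
  expect_lt(abs((est[["a2.trait"]] + est[["d2.trait"]]) - 0.65), 0.05)
  expect_lt(abs((est[["a2.liab"]] + est[["d2.liab"]]) - 0.65), 0.05)
  expect_lt(abs(est[["rE"]] - 0.25), 0.05)
  for (z in c("MZ", "DZ"))
    expect_lt(max(abs(cov2cor(implied_moments(sp, z)) -
                        cov2cor(implied_moments(f$spec, z)))), 0.05)
})

test_that("sibling-interaction fits reproduce the generating moments", {
  gen <- twin_spec(a2 = c(0.5, 0.55), d2 = c(0.15, 0.15), rA = 0.5, rD = 0.3,
                   rE = 0.25, s = c(0.12, 0.12),
                   tau = c(M = qnorm(0.85), F = qnorm(0.85)),
                   n_pairs = c(MZM = 4000, MZF = 4000, DZM = 4000, DZF = 4000),
                   seed = 222)
  pt <- simulate_twin_pairs(gen)
  f <- fit_structural(pt, "trait", "diagnosis", family = "ADE-s",
                      restarts = 1, seed = 9)
  for (z in c("MZ", "DZ")) {
    Rg <- cov2cor(implied_moments(gen, z))
    Rf <- cov2cor(implied_moments(f$spec, z))
    expect_lt(max(abs(Rg - Rf)), 0.05)
  }
})

test_that("fitting with free trait scale matches fitting after standardisation", {
  sp <- twin_spec(a2 = c(0.6, 0.7), rA = 0.5, rE = 0.3,
                  tau = c(M = 1.1, F = 1.1),
                  n_pairs = c(MZM = 3000, MZF = 3000, DZM = 3000, DZF = 3000),
                  seed = 55)
  pt <- simulate_twin_pairs(sp)
  pt$trait <- 7 + 3.2 * pt$trait  # arbitrary raw scale
  f_std <- fit_structural(pt, "trait", "diagnosis", "AE", restarts = 1, seed = 2)
  f_free <- fit_structural(pt, "trait", "diagnosis", "AE", standardize = FALSE,
                           restarts = 1, seed = 2)
  expect_lt(abs(f_std$derived$rG - f_free$derived$rG), 0.01)
  expect_lt(abs(coef(f_free)[["mu.trait"]] - 7), 0.2)
  expect_lt(abs(coef(f_free)[["sd.trait"]] - 3.2), 0.2)
})

test_that("model selection follows the BIC/LRT rule", {
  # identical loglik with one fewer parameter favours the reduction
  mk <- function(family, loglik, npar, N = 1000) {
    structure(list(family = family, loglik = loglik, npar = npar, N = N,
                   BIC = -2 * loglik + npar * log(N)), class = "twin_fit")
  }
  sel <- select_model(list(ACE = mk("ACE", -500, 9), AE = mk("AE", -500, 8)))
  expect_equal(sel$lrt_stat[2], 0)
  expect_equal(sel$lrt_p[2], 1)
  expect_true(sel$favored[sel$model == "AE"])
  # chi-square boundary: delta(-2lnL) = 3.84 on 1 df sits at p = 0.05
  sel2 <- select_model(list(full = mk("ACE", -500, 9),
                            red = mk("AE", -501.92, 8)))
  expect_equal(sel2$lrt_p[2], 0.05, tolerance = 0.001)
  expect_error(lrt_twin(mk("AE", -500, 8), mk("ACE", -499, 9)), "nested")
})

test_that("probandwise concordance follows 2C/(2C+D)", {
  df <- do.call(rbind, lapply(1:30, function(i) {
    data.frame(pair_id = sprintf("p%02d", i), twin_order = 1:2,
               zygosity = "MZM", sex = "M", age_cohort = 9L,
               dx = if (i <= 10) c(1L, 1L) else c(1L, 0L))
  }))
  pt <- phenotype_table(df, diagnoses = "dx")
  cc <- probandwise_concordance(pt, "dx")
  expect_equal(cc$concordance[cc$zygosity == "MZ"], 0.5)  # C=10, D=20
  expect_true(is.na(cc$concordance[cc$zygosity == "DZ"]))
  # D = 0 gives concordance 1
  df$dx <- 1L
  cc2 <- probandwise_concordance(phenotype_table(df, diagnoses = "dx"), "dx")
  expect_equal(cc2$concordance[1], 1)
})

test_that("MZ concordance exceeds DZ under genetic liability", {
  sp <- twin_spec(a2 = c(0.5, 0.8), rA = 0.3, rE = 0.1,
                  tau = c(M = qnorm(0.95), F = qnorm(0.95)),
                  n_pairs = c(MZM = 25000, MZF = 25000, DZM = 25000,
                              DZF = 25000), seed = 808)
  pt <- simulate_twin_pairs(sp)
  cc <- probandwise_concordance(pt, "diagnosis")
  expect_gt(cc$concordance[cc$zygosity == "MZ"],
            cc$concordance[cc$zygosity == "DZ"])
})

test_that("saturated model recovers the generating correlations", {
  sp <- asd_spec(n_mz = 6000, n_dz = 6000, seed = 71)
  pt <- simulate_twin_pairs(sp)
  sat <- fit_saturated(pt, "trait", "diagnosis")
  Rmz <- cov2cor(implied_moments(sp, "MZ"))
  Rdz <- cov2cor(implied_moments(sp, "DZ"))
  g <- function(stat, cls) sat$est[sat$statistic == stat & sat$class == cls]
  expect_lt(abs(g("rPh", "all") - Rmz[1, 2]), 0.05)
  expect_lt(abs(g("r_trait", "MZ") - Rmz[1, 3]), 0.03)
  expect_lt(abs(g("r_trait", "DZ") - Rdz[1, 3]), 0.03)
  expect_lt(abs(g("r_cross", "MZ") - Rmz[1, 4]), 0.06)
  # MZ-only input reports DZ entries as missing
  mz_only <- pt[pt$zygosity %in% c("MZM", "MZF"), ]
  mz_only <- phenotype_table(as.data.frame(mz_only), "trait", "diagnosis")
  sat2 <- suppressWarnings(fit_saturated(mz_only, "trait", "diagnosis"))
  expect_true(all(is.na(sat2$est[sat2$class == "DZ"])))
})

test_that("decomposition of the phenotypic correlation is exact under AE", {
  # a2 0.74/0.81, rA 0.48, e2 0.26/0.19, rE 0.353:
  # rPh = 0.48*sqrt(0.74*0.81) + 0.353*sqrt(0.26*0.19) = 0.450
  sp <- twin_spec(a2 = c(0.74, 0.81), rA = 0.48, rE = 0.353)
  fit <- structure(list(spec = sp), class = "twin_fit")
  fit$derived <- twinprs:::.derived_quantities(fit)
  d <- decompose_phenotypic_correlation(fit)
  rPh <- 0.48 * sqrt(0.74 * 0.81) + 0.353 * sqrt(0.26 * 0.19)
  expect_equal(d$rPh, rPh, tolerance = 1e-12)
  expect_equal(d$genetic_share, 0.48 * sqrt(0.74 * 0.81) / rPh,
               tolerance = 1e-12)
  expect_equal(sum(d$shares), 1, tolerance = 1e-12)
  # rE = 0 puts the whole correlation on the genetic side
  sp0 <- twin_spec(a2 = c(0.74, 0.81), rA = 0.48, rE = 0)
  fit0 <- structure(list(spec = sp0), class = "twin_fit")
  fit0$derived <- twinprs:::.derived_quantities(fit0)
  expect_equal(decompose_phenotypic_correlation(fit0)$genetic_share, 1,
               tolerance = 1e-12)
})
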