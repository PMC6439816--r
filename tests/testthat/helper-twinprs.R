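# shared fixtures and independent oracles

# multivariate normal density, written out so it is independent of the
# package's likelihood code
dmvn <- function(x, sigma) {
  k <- length(x)
  Q <- solve(sigma)
  exp(-0.5 * (k * log(2 * pi) + determinant(sigma)$modulus +
                drop(t(x) %*% Q %*% x)))
}

# brute-force pair log-likelihood: numerically integrate the joint normal
# density over the rectangle implied by the observed diagnoses, at the
# observed trait values; missing elements marginalised by subsetting.
oracle_pair_loglik <- function(R, tr, dx, tau) {
  ti <- c(1, 3)[!is.na(tr)]
  li <- c(2, 4)[!is.na(dx)]
  tv <- tr[!is.na(tr)]
  dv <- dx[!is.na(dx)]
  tauv <- tau[!is.na(dx)]
  obs <- c(ti, li)
  S <- R[obs, obs, drop = FALSE]
  nt <- length(ti); nl <- length(li)
  lim <- function(j) if (dv[j] == 1) c(tauv[j], 8) else c(-8, tauv[j])
  if (nl == 2) {
    l1 <- lim(1); l2 <- lim(2)
    f <- function(u, v) {
      out <- u
      for (i in seq_along(u)) out[i] <- dmvn(c(tv, u[i], v[i]), S)
      out
    }
    val <- pracma::integral2(f, l1[1], l1[2], l2[1], l2[2],
                             reltol = 1e-10)$Q
  } else if (nl == 1) {
    l1 <- lim(1)
    f <- function(u) vapply(u, function(ui) dmvn(c(tv, ui), S), 0)
    val <- stats::integrate(f, l1[1], l1[2], rel.tol = 1e-11)$value
  } else {
    val <- dmvn(tv, S)
  }
  log(val)
}

# standard ASD-like operating point used across tests
asd_spec <- function(n_mz = 2000, n_dz = 2000, seed = 1L, ...) {
  rA <- (0.45 - 0.353 * sqrt(0.26 * 0.19)) / sqrt(0.74 * 0.81)
  twin_spec(a2 = c(0.74, 0.81), rA = rA, rE = 0.353,
            tau = c(M = qnorm(1 - 0.009), F = qnorm(1 - 0.009)),
            n_pairs = c(MZM = ceiling(n_mz / 2), MZF = floor(n_mz / 2),
                        DZM = ceiling(n_dz / 3), DZF = floor(n_dz / 3),
                        DZOS = n_dz - ceiling(n_dz / 3) - floor(n_dz / 3)),
            seed = seed, ...)
}

# tiny well-formed two-row phenotype data frame
tiny_pheno_df <- function() {
  data.frame(pair_id = c("p1", "p1"), twin_order = 1:2, zygosity = "MZM",
             sex = "M", age_cohort = 9L, asd_trait = c(3, 5),
             asd_dx = c(0L, 1L))
}

published_table <- function(name) {
  read.delim(system.file("extdata", name, package = "twinprs"),
             stringsAsFactors = FALSE)
}
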