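#' Specify a bivariate trait/liability twin model
#'
#' Collects the generating (or fitted) parameters of a joint
#' categorical/continuous twin model: per-phenotype variance decompositions
#' into additive genetic (A), nonadditive genetic (D), shared environment (C)
#' and nonshared environment (E); the correlations between the two
#' phenotypes' A/D/C/E factors; sex-specific liability thresholds; and, for
#' simulation, pair counts per zygosity-by-sex group and missingness rates.
#'
#' The E proportion is derived as `1 - a2 - c2 - d2` and must be positive.
#' C and D cannot both be nonzero in one model (they are not jointly
#' identified in a twin-only design). Sibling interaction `s` is a reciprocal
#' path between co-twins' same-phenotype latent variables, applied to the
#' trait and/or the liability.
#'
#' @param a2,c2,d2 length-2 numeric (trait, liability) variance proportions
#' @param rA,rC,rD,rE factor correlations between the two phenotypes
#' @param s length-2 sibling-interaction paths (trait, liability)
#' @param tau liability thresholds, named `c(M = , F = )`
#' @param n_pairs named counts for groups `MZM, DZM, MZF, DZF, DZOS`
#' @param missing_rate named rates `c(trait = , diagnosis = )`
#' @param seed non-negative integer seed used by [simulate_twin_pairs()]
#' @return an object of class `twin_spec`
#' @export
twin_spec <- function(a2 = c(0.5, 0.5), c2 = c(0, 0), d2 = c(0, 0),
                      rA = 0, rC = 0, rD = 0, rE = 0,
                      s = c(0, 0),
                      tau = c(M = qnorm(0.99), F = qnorm(0.99)),
                      n_pairs = c(MZM = 0, DZM = 0, MZF = 0, DZF = 0, DZOS = 0),
                      missing_rate = c(trait = 0, diagnosis = 0),
                      seed = 1L) {
  a2 <- rep_len(as.numeric(a2), 2L)
  c2 <- rep_len(as.numeric(c2), 2L)
  d2 <- rep_len(as.numeric(d2), 2L)
  s  <- rep_len(as.numeric(s), 2L)
  e2 <- 1 - a2 - c2 - d2
  if (any(c(a2, c2, d2) < 0) || any(e2 <= 0))
    stop("variance proportions must be >= 0 with e2 = 1 - a2 - c2 - d2 > 0")
  if (any(c2 > 0) && any(d2 > 0))
    stop("C and D cannot both be present in one model (ACE vs ADE)")
  for (r in c(rA, rC, rD, rE)) if (abs(r) > 1) stop("factor correlations must lie in [-1, 1]")
  if (any(abs(s) >= 1)) stop("sibling interaction must lie in (-1, 1)")
  if (is.null(names(tau))) names(tau) <- c("M", "F")[seq_along(tau)]
  tau <- c(M = unname(tau["M"]), F = unname(tau[ifelse(is.na(tau["F"]), "M", "F")]))
  if (any(!is.finite(tau))) stop("thresholds must be finite")
  np <- c(MZM = 0, DZM = 0, MZF = 0, DZF = 0, DZOS = 0)
  np[names(n_pairs)] <- n_pairs
  if (any(np < 0)) stop("pair counts must be >= 0")
  mr <- c(trait = 0, diagnosis = 0)
  mr[names(missing_rate)] <- missing_rate
  structure(list(a2 = a2, c2 = c2, d2 = d2, e2 = e2,
                 rA = rA, rC = rC, rD = rD, rE = rE, s = s,
                 tau = tau, n_pairs = np, missing_rate = mr,
                 seed = as.integer(seed)),
            class = "twin_spec")
}

#' @export
print.twin_spec <- function(x, ...) {
  cat("Bivariate twin-model specification (trait, liability)\n")
  cat(sprintf("  a2 = (%.3f, %.3f)  c2 = (%.3f, %.3f)  d2 = (%.3f, %.3f)  e2 = (%.3f, %.3f)\n",
              x$a2[1], x$a2[2], x$c2[1], x$c2[2], x$d2[1], x$d2[2], x$e2[1], x$e2[2]))
  cat(sprintf("  rA = %.3f  rC = %.3f  rD = %.3f  rE = %.3f  s = (%.3f, %.3f)\n",
              x$rA, x$rC, x$rD, x$rE, x$s[1], x$s[2]))
  cat(sprintf("  thresholds: tau_M = %.3f (prev %.2f%%), tau_F = %.3f (prev %.2f%%)\n",
              x$tau["M"], 100 * pnorm(-x$tau["M"]), x$tau["F"], 100 * pnorm(-x$tau["F"])))
  cat("  pairs:", paste(names(x$n_pairs), x$n_pairs, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# cross-twin correlation of each latent factor, by zygosity
.cross_coef <- function(zygosity) {
  switch(zygosity,
         MZ = c(A = 1, D = 1,    C = 1, E = 0),
         DZ = c(A = 0.5, D = 0.25, C = 1, E = 0),
         stop("zygosity must be 'MZ' or 'DZ'"))
}

#' Model-implied cross-twin covariance matrix
#'
#' Builds the 4x4 covariance matrix of `(trait1, liability1, trait2,
#' liability2)` implied by a [twin_spec()] for one zygosity class. Each
#' latent component contributes a PSD block: the within-person 2x2 block
#' `[[v_t, r*sqrt(v_t v_l)], [., v_l]]` appears on the diagonal and, scaled
#' by the component's cross-twin coefficient (A: 1 MZ / 0.5 DZ; D: 1 / 0.25;
#' C: 1 / 1; E: 0 / 0), off the diagonal. Sibling interaction enters as
#' reciprocal phenotype-on-phenotype paths between co-twins: with path
#' matrix `B` holding `s` on the cross-twin same-phenotype cells, the
#' observed covariance is `(I - B)^-1 Sigma (I - B)^-T`, which inflates the
#' variances (for one phenotype with all-nonshared latent variance,
#' var = (1 + s^2)/(1 - s^2)^2 and cross-twin cov = 2s/(1 - s^2)^2).
#'
#' With `s = 0` the diagonal is exactly 1 and the matrix is a correlation
#' matrix; with `s != 0` callers needing correlations should apply
#' [stats::cov2cor()].
#'
#' @param spec a [twin_spec()]
#' @param zygosity `"MZ"` or `"DZ"`
#' @return 4x4 symmetric PSD matrix with dimnames
#'   `c("trait1","liab1","trait2","liab2")`
#' @export
implied_moments <- function(spec, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  cc <- .cross_coef(zygosity)
  v <- rbind(A = spec$a2, D = spec$d2, C = spec$c2, E = spec$e2)
  r <- c(A = spec$rA, D = spec$rD, C = spec$rC, E = spec$rE)
  sigma <- matrix(0, 4, 4)
  for (k in rownames(v)) {
    w <- matrix(c(v[k, 1], r[k] * sqrt(v[k, 1] * v[k, 2]),
                  r[k] * sqrt(v[k, 1] * v[k, 2]), v[k, 2]), 2, 2)
    sigma <- sigma + rbind(cbind(w, cc[k] * w), cbind(cc[k] * w, w))
  }
  if (any(spec$s != 0)) {
    B <- matrix(0, 4, 4)
    B[1, 3] <- B[3, 1] <- spec$s[1]
    B[2, 4] <- B[4, 2] <- spec$s[2]
    inv <- solve(diag(4) - B)
    sigma <- inv %*% sigma %*% t(inv)
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("parameter combination implies a non-PSD cross-twin covariance")
  dimnames(sigma) <- rep(list(c("trait1", "liab1", "trait2", "liab2")), 2)
  (sigma + t(sigma)) / 2
}
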