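#' Simulate-and-refit at a published operating point
#'
#' Convenience wrapper for the estimator-validation exercise used throughout
#' the package's checks: given a bivariate AE operating point stated in
#' terms of the trait heritability, the diagnosis liability heritability,
#' the diagnosis prevalence, the nonshared-environment correlation and the
#' phenotypic correlation, it solves for the generating genetic correlation
#' through the decomposition identity
#' `rPh = rA*sqrt(a2_t*a2_l) + rE*sqrt(e2_t*e2_l)`, simulates twin pairs at
#' that point, refits the joint AE model by maximum likelihood, and returns
#' the recovered quantities.
#'
#' @param trait_h2,liab_h2 heritabilities of trait and diagnosis liability
#' @param prevalence diagnosis prevalence (both sexes)
#' @param rE nonshared-environment correlation
#' @param rPh target phenotypic (trait-liability) correlation
#' @param n_mz,n_dz pair counts (MZ split half male/female; DZ split in
#'   thirds male/female/opposite-sex)
#' @param seed master seed
#' @param restarts optimiser restarts
#' @return list: `rA_generating`, `fit` (the `twin_fit`), `rG_hat`,
#'   `rE_hat`, `rPh_hat`
#' @export
recover_genetic_correlation <- function(trait_h2, liab_h2, prevalence,
                                        rE, rPh, n_mz = 100000,
                                        n_dz = 100000, seed = 1L,
                                        restarts = 2L) {
  e2t <- 1 - trait_h2; e2l <- 1 - liab_h2
  rA <- (rPh - rE * sqrt(e2t * e2l)) / sqrt(trait_h2 * liab_h2)
  if (abs(rA) > 1) stop("operating point implies |rA| > 1")
  tau <- qnorm(1 - prevalence)
  sp <- twin_spec(a2 = c(trait_h2, liab_h2), rA = rA, rE = rE,
                  tau = c(M = tau, F = tau),
                  n_pairs = c(MZM = ceiling(n_mz / 2), MZF = floor(n_mz / 2),
                              DZM = ceiling(n_dz / 3), DZF = floor(n_dz / 3),
                              DZOS = n_dz - ceiling(n_dz / 3) - floor(n_dz / 3)),
                  seed = substream_seed(seed, "operating_point"))
  pt <- simulate_twin_pairs(sp)
  fit <- fit_structural(pt, "trait", "diagnosis", family = "AE",
                        restarts = restarts, seed = seed)
  list(rA_generating = rA, fit = fit, rG_hat = fit$derived$rG,
       rE_hat = fit$derived$rE, rPh_hat = fit$derived$rPh)
}
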