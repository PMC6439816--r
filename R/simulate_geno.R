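#' Specify an additive polygenic simulation
#'
#' Parameters of the genotype/summary-statistics generator: panel size,
#' number of causal variants, allele-frequency range, block LD structure
#' (variants are grouped into blocks whose haplotype alleles share a
#' Gaussian-copula correlation), per-causal-variant effect-size SD, the
#' discovery-study sample size, the proportion of outcome variance explained
#' by the true score, and an optional two-subpopulation divergence used to
#' construct stratification confounding.
#'
#' @param m_variants panel size
#' @param n_causal number of variants with nonzero true effect
#' @param maf_range ancestral allele-frequency range, in (0, 0.5]
#' @param block_size variants per LD block
#' @param block_r latent haplotype correlation within a block, in [0, 1)
#' @param effect_sd SD of true effects at causal variants (per-allele scale)
#' @param n_discovery discovery GWAS sample size
#' @param h2_score proportion of target-outcome variance from the true score
#' @param fst Balding-Nichols-style divergence between two subpopulations
#'   (0 = homogeneous population)
#' @param strat_shift mean shift of the outcome in subpopulation 2, for
#'   confounding constructions
#' @param seed master seed
#' @return object of class `polygenic_spec`
#' @export
polygenic_spec <- function(m_variants = 1000L, n_causal = 50L,
                           maf_range = c(0.05, 0.5), block_size = 10L,
                           block_r = 0.3, effect_sd = 0.05,
                           n_discovery = 50000L, h2_score = 0.05,
                           fst = 0, strat_shift = 0, seed = 1L) {
  if (n_causal > m_variants) stop("n_causal must be <= m_variants")
  if (any(maf_range <= 0) || any(maf_range > 0.5)) stop("maf_range must lie in (0, 0.5]")
  if (block_r < 0 || block_r >= 1) stop("block_r must lie in [0, 1)")
  if (h2_score < 0 || h2_score >= 1) stop("h2_score must lie in [0, 1)")
  structure(list(m_variants = as.integer(m_variants), n_causal = as.integer(n_causal),
                 maf_range = maf_range, block_size = as.integer(block_size),
                 block_r = block_r, effect_sd = effect_sd,
                 n_discovery = as.integer(n_discovery), h2_score = h2_score,
                 fst = fst, strat_shift = strat_shift, seed = as.integer(seed)),
            class = "polygenic_spec")
}

# ancestral frequencies, per-subpop frequencies, causal effects
.variant_truth <- function(pspec) {
  set.seed(substream_seed(pspec$seed, "variant_truth"))
  m <- pspec$m_variants
  p0 <- runif(m, pspec$maf_range[1], pspec$maf_range[2])
  if (pspec$fst > 0) {
    a <- p0 * (1 - pspec$fst) / pspec$fst
    b <- (1 - p0) * (1 - pspec$fst) / pspec$fst
    p1 <- pmin(pmax(rbeta(m, a, b), 0.01), 0.99)
    p2 <- pmin(pmax(rbeta(m, a, b), 0.01), 0.99)
  } else p1 <- p2 <- p0
  beta <- numeric(m)
  causal <- if (pspec$n_causal > 0) sort(sample.int(m, pspec$n_causal)) else integer(0)
  beta[causal] <- rnorm(length(causal), 0, pspec$effect_sd)
  data.frame(id = sprintf("rs%05d", seq_len(m)),
             chrom = 1L, pos = 10000L * seq_len(m),
             allele1 = "A", allele2 = "C",
             p0 = p0, p1 = p1, p2 = p2, beta_true = beta,
             causal = seq_len(m) %in% causal)
}

# one haplotype set: n_hap x m binary matrix with block-copula LD, given
# per-haplotype subpopulation assignment
.draw_haplotypes <- function(n_hap, truth, pspec, pop) {
  m <- nrow(truth)
  H <- matrix(0L, n_hap, m)
  blocks <- split(seq_len(m), (seq_len(m) - 1) %/% pspec$block_size)
  sr <- sqrt(pspec$block_r); se <- sqrt(1 - pspec$block_r)
  for (b in blocks) {
    u <- rnorm(n_hap)
    z <- sr * u + se * matrix(rnorm(n_hap * length(b)), n_hap)
    thr <- rbind(qnorm(truth$p1[b]), qnorm(truth$p2[b]))
    H[, b] <- (z < thr[pop, , drop = FALSE]) + 0L
  }
  H
}

#' Simulate twin-pair genotypes with block LD
#'
#' Draws parental haplotypes under Hardy-Weinberg equilibrium with
#' block-structured LD (a Gaussian copula with the spec's within-block
#' correlation, thresholded at each variant's allele frequency) and
#' transmits one haplotype per parent to each child. MZ co-twins receive
#' identical genotypes; DZ co-twins draw their transmissions independently,
#' giving an expected cross-twin dosage correlation of 0.5 at every locus.
#' With `fst > 0`, pairs are split between two subpopulations with diverged
#' allele frequencies.
#'
#' Dosages count `allele1` (the effect-allele column of the generated
#' summary statistics). Individual ids are `<pair_id>_<twin_order>`.
#'
#' @param pspec a [polygenic_spec()]
#' @param pairs a [phenotype_table()] defining pair ids and zygosity
#' @return a [genotype_data()] with attributes `truth` (per-variant
#'   generating table) and `subpop` (per-individual 1/2)
#' @export
simulate_genotypes <- function(pspec, pairs) {
  stopifnot(inherits(pspec, "polygenic_spec"), inherits(pairs, "phenotype_table"))
  truth <- .variant_truth(pspec)
  w <- pair_wide(pairs, character(0))
  npair <- nrow(w)
  set.seed(substream_seed(pspec$seed, "genotypes"))
  pair_pop <- if (pspec$fst > 0) rep_len(1:2, npair) else rep(1L, npair)
  # 4 parental haplotypes per pair
  hap_pop <- rep(pair_pop, each = 4L)
  H <- .draw_haplotypes(4L * npair, truth, pspec, hap_pop)
  # transmission chosen independently per LD block (free recombination
  # between blocks, none within)
  base <- 4L * (seq_len(npair) - 1L)
  mz <- w$zygosity %in% c("MZM", "MZF")
  m <- nrow(truth)
  blocks <- split(seq_len(m), (seq_len(m) - 1) %/% pspec$block_size)
  d1 <- matrix(0L, npair, m); d2 <- matrix(0L, npair, m)
  pick <- function() base + sample(1:2, npair, replace = TRUE)
  for (b in blocks) {
    mo1 <- pick(); fa1 <- pick() + 2L        # twin 1 transmissions
    mo2 <- pick(); fa2 <- pick() + 2L        # twin 2 (used only for DZ)
    mo2[mz] <- mo1[mz]; fa2[mz] <- fa1[mz]
    d1[, b] <- H[mo1, b, drop = FALSE] + H[fa1, b, drop = FALSE]
    d2[, b] <- H[mo2, b, drop = FALSE] + H[fa2, b, drop = FALSE]
  }
  dosage <- matrix(0L, 2L * npair, nrow(truth))
  dosage[seq(1, 2 * npair, 2), ] <- d1
  dosage[seq(2, 2 * npair, 2), ] <- d2
  ids <- as.vector(rbind(paste0(w$pair_id, "_1"), paste0(w$pair_id, "_2")))
  g <- genotype_data(ids, truth[c("id", "chrom", "pos", "allele1", "allele2")],
                     dosage)
  attr(g, "truth") <- truth
  attr(g, "subpop") <- rep(pair_pop, each = 2L)
  g
}

#' Simulate discovery GWAS summary statistics
#'
#' Adds estimation noise to the true per-allele effects:
#' `beta_hat = beta_true + N(0, se^2)` with
#' `se = sqrt(1 / (2 * maf * (1 - maf) * n_discovery))` (the standard
#' large-sample SE of a per-allele regression coefficient on a standardised
#' outcome), and two-sided Wald p-values.
#'
#' @param pspec a [polygenic_spec()]
#' @param truth per-variant truth table as attached by [simulate_genotypes()]
#'   (columns `id, chrom, pos, allele1, allele2, p0, beta_true`)
#' @return a [gwas_sumstats()]
#' @export
simulate_discovery_sumstats <- function(pspec, truth) {
  set.seed(substream_seed(pspec$seed, "sumstats"))
  maf <- pmin(truth$p0, 1 - truth$p0)
  se <- sqrt(1 / (2 * maf * (1 - maf) * pspec$n_discovery))
  beta_hat <- truth$beta_true + rnorm(nrow(truth), 0, se)
  p <- 2 * pnorm(-abs(beta_hat / se))
  gwas_sumstats(data.frame(
    id = truth$id, chrom = truth$chrom, pos = truth$pos,
    effect_allele = truth$allele1, other_allele = truth$allele2,
    beta = beta_hat, se = se, p = pmax(p, 1e-300), n = pspec$n_discovery))
}

#' Attach genetically driven outcomes to simulated genotypes
#'
#' Builds a continuous outcome as `sqrt(h2) * standardised true score +
#' sqrt(1 - h2) * noise` (so the squared correlation between the true score
#' and the outcome is `h2` by construction), a binary outcome by
#' thresholding the same liability at `tau`, and, when the spec carries a
#' `strat_shift`, adds that shift to subpopulation 2 to create
#' stratification confounding.
#'
#' @param geno a [genotype_data()] from [simulate_genotypes()]
#' @param truth the truth table attached to `geno`
#' @param pspec the [polygenic_spec()]
#' @param tau liability threshold for the binary outcome
#' @return data frame: `id`, `score_true`, `outcome`, `outcome_bin`, `subpop`
#' @export
attach_genetic_phenotype <- function(geno, truth, pspec, tau = qnorm(0.99)) {
  set.seed(substream_seed(pspec$seed, "phenotype"))
  d <- geno$dosage
  d[is.na(d)] <- 0
  g <- as.vector(d %*% truth$beta_true)
  gz <- if (sd(g) > 0) (g - mean(g)) / sd(g) else g
  n <- length(gz)
  h2 <- pspec$h2_score
  liab <- sqrt(h2) * gz + sqrt(1 - h2) * rnorm(n)
  pop <- attr(geno, "subpop")
  if (is.null(pop)) pop <- rep(1L, n)
  if (pspec$strat_shift != 0) liab <- liab + pspec$strat_shift * (pop == 2L)
  data.frame(id = geno$ids, score_true = gz, outcome = liab,
             outcome_bin = as.integer(liab > tau), subpop = pop,
             stringsAsFactors = FALSE)
}
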