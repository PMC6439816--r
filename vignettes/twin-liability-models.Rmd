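---
title: "Joint categorical/continuous twin models and polygenic score pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint categorical/continuous twin models and polygenic score pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinprs)
```

## The scientific problem

Psychiatric diagnoses are rare and binary; the traits they sit on top of are
common and continuous. A central question in psychiatric genetics is how much
of the genetic liability to a clinical diagnosis (autism spectrum disorder,
ADHD, tic disorders, anxiety, depression, intellectual disability) is shared
with ordinary population variation in the corresponding trait. Two designs
address it: the classical twin design, which contrasts monozygotic (MZ) and
dizygotic (DZ) pair resemblance, and polygenic risk scores (PRS), which carry
common-variant risk from a discovery GWAS of the diagnosis into a target
sample measured on the trait. `twinprs` implements both engines, together
with a synthetic cohort generator that gives every stage a known ground
truth.

## The joint categorical/continuous twin model

For one twin pair, write the trait values of the two twins as $t_1, t_2$ and
the latent diagnosis liabilities as $\ell_1, \ell_2$. The model treats
$(t_1, \ell_1, t_2, \ell_2)$ as multivariate normal. Each phenotype's
variance is decomposed into additive genetic (A), nonadditive genetic (D) or
shared environment (C), and nonshared environment (E) proportions; across
co-twins the components correlate 1 (MZ) / 0.5 (DZ) for A, 1 / 0.25 for D,
1 / 1 for C and 0 / 0 for E. The same components carry the cross-phenotype
structure through the factor correlations $r_A$, $r_D$ or $r_C$, and $r_E$.
A diagnosis is observed when the liability exceeds a sex-specific threshold
$\tau_{sex}$, so the prevalence fixes the threshold via
$\tau = \Phi^{-1}(1 - K)$.

The per-pair likelihood factorises exactly: the observed trait values
contribute a bivariate-normal density, and the observed diagnoses contribute
the conditional bivariate-normal rectangle probability given the traits.
Missing elements are marginalised by dropping their coordinates. The
rectangle probabilities use the package's own vectorised implementation of
the standard Gauss–Legendre algorithm for the bivariate normal CDF
(`pbvn()`, absolute accuracy around 1e-15), because cell probabilities for
diagnoses with prevalence below 1% sit far in the tail and naive
quadrature loses precision exactly where the likelihood needs it most.

Sibling interaction (`-s` families) is modelled as a reciprocal path $s$
between co-twins' same-phenotype latent variables: with path matrix $B$,
the observed covariance is $(I-B)^{-1} \Sigma (I-B)^{-\top}$. This is the
standard reciprocal-interaction parameterisation; it inflates MZ relative
to DZ resemblance and can mimic dominance, which is why model selection
compares ADE-s against its reductions. The interaction is applied to both
the trait and the liability by default, each with its own path coefficient,
since nothing in the design forces them to share one.

### Estimation

`fit_structural()` maximises the summed pair log-likelihood over
transformed parameters: variance proportions through a softmax (logistic
for two components), correlations through `atanh`, thresholds free. The
search is quasi-Newton (BFGS) from a moment-based start (Falconer-style
heritability from the cross-twin correlations, prevalence-based
thresholds), followed by a Nelder–Mead polish that guards against
line-search stalls on flat regions, with jittered restarts
(`restarts`, default 5). MZ pairs are pooled across sexes and all DZ pairs
(same-sex and opposite-sex) share structural parameters: the design is
underpowered for sex-specific variance components, so sex enters only
through the thresholds and the trait standardisation.

Traits are standardised by sex before fitting (`standardize = TRUE`);
alternatively the trait mean and SD can be fitted as free parameters, and
the two routes agree on the genetic correlation to well under 0.01 (a
regression test enforces this). `N` in the BIC is the number of twin pairs
contributing any observed data.

Derived quantities: the genetic correlation `rG` (for ADE families both
the A-only correlation and the correlation of total genetic deviations
A+D are reported, since a single "genetic correlation" is ambiguous
there); the model-implied phenotypic correlation
$r_{Ph} = \sum_k r_k \sqrt{v_{k,t}\, v_{k,\ell}}$; and the share of
$r_{Ph}$ attributable to each component. With sibling interaction the
shares are computed by propagating each latent component separately
through $(I-B)^{-1}\Sigma_k(I-B)^{-\top}$, which is exact by linearity.

### Model selection and descriptives

`fit_saturated()` produces the descriptive correlation set: the polyserial
trait–diagnosis correlation pooled over everyone, and per zygosity class
the Pearson cross-twin trait correlation (double-entered, enforcing equal
means/variances across twin order), the tetrachoric diagnosis correlation
(pooled thresholds), and the polyserial cross-twin cross-trait
correlation. `select_model()` implements the reporting rule: lowest BIC
among the full model and all nested reductions whose likelihood-ratio test
against the full model is non-significant; ties go to the smaller model.
LRT p-values at boundary constraints (a variance pinned at 0) are reported
from the plain $\chi^2$ reference without a mixture correction — a
documented, conservative caveat. `probandwise_concordance()` reports
$2C/(2C+D)$ per zygosity.

Profile-likelihood confidence intervals for the factor correlations are
available on demand through `confint()`, which refits with the target
parameter fixed and brackets the $\chi^2(1)$ cutoff; they are not computed
during fitting because each bound costs a sequence of refits.

## The synthetic cohort generator

`twin_spec()` + `simulate_twin_pairs()` draw pairs from exactly the model
above, per zygosity-by-sex group (MZM, DZM, MZF, DZF, DZOS), with MCAR
missingness and a fixed-seed substream per operation, so identical specs
reproduce bit-identically. Defaults mirror the study conditions the package
is validated against: trait heritabilities around 0.7, liability
heritabilities 0.8–0.95, prevalences 0.3%–3.3%, and phenotypic
correlations 0.2–0.7.

`polygenic_spec()` + `simulate_genotypes()` build genotypes at the
haplotype level: founder haplotypes are drawn from a Gaussian copula with
exchangeable within-block correlation (thresholded at each variant's
frequency), children receive one haplotype per parent with transmission
chosen independently per block (free recombination between blocks, none
within). MZ co-twins get identical genotypes; DZ co-twins share parental
transmission, giving the Mendelian expected dosage correlation of 0.5.
Optional two-subpopulation frequency divergence (Balding–Nichols beta
draws at a given differentiation level) plus an outcome mean shift creates
stratification confounding on demand. `simulate_discovery_sumstats()` adds
estimation noise with the large-sample SE
$\sqrt{1/(2\,\mathrm{maf}(1-\mathrm{maf})\,n)}$ and Wald p-values.

What the generator does **not** emulate: realistic allele-frequency
spectra and LD decay, imputation uncertainty, X-linked variation,
assortative mating, sex-specific genetic architectures, and longitudinal
measurement. Passing tests therefore demonstrate the correctness of the
estimators under the stated generative model, not robustness to every
feature of real cohort data.

## The PRS pipeline

The pipeline follows common GWAS practice: allele harmonisation to the
target panel (sign flips for swapped alleles; A/T and C/G variants dropped
as strand-ambiguous), greedy LD clumping by ascending p-value
(defaults r² = 0.1 within 250 kb, deterministic tie-break by p, position,
id), weighted scoring at a grid of p-value selection thresholds
({5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.5, 1}, primary 0.5), with missing
dosages mean-imputed from the target-sample effect-allele frequency, and
z-standardisation (denominator n−1). Stratification covariates are the top
10 principal components of the MAF-filtered, LD-pruned,
frequency-standardised dosage matrix; one member of each MZ pair enters
the decomposition and the co-twin inherits its coordinates, because
duplicated genotype rows would distort the eigenstructure.

Association testing uses estimating equations with an independence working
correlation: GLM point estimates with a cluster-robust sandwich variance
summing score contributions within twin pairs. With singleton clusters
this is exactly the HC0 sandwich (a test pins the equality against the
reference implementation in the `sandwich` package). Odds ratios use
`exp(beta ± 1.96 SE)`. Variance explained is incremental over the
covariate-only model: ΔR² for linear outcomes and, for logistic outcomes,
the increment in the squared correlation between outcome and fitted
probability — an explicitly documented proxy, since no single R² is
canonical for binary outcomes. Multiple testing is controlled by
Benjamini–Hochberg FDR across the primary-threshold full-sample tests as
one family; diagnosed-exclusion reruns form their own family.

## Numerical and design choices

* **Optimiser tolerances**: relative log-likelihood tolerance 1e-12,
  maximum 500 BFGS iterations plus a 400-step simplex polish; restarts
  jitter the transformed start by N(0, 0.4).
* **Boundary handling**: tetrachoric/polyserial estimates beyond |0.998|
  are reported as ±1 with a boundary flag and no SE; zero-margin tables
  warn and return `NA`. Variance proportions within 1e-3 of 0 or 1 are
  flagged on the fit object.
* **Identifiability**: the A/D split within one phenotype is weakly
  identified at realistic sample sizes (DZ D-correlation is only 0.25);
  total genetic variance (a² + d²) and the implied correlation matrices
  are the stable summaries, and the test suite checks ADE fits at that
  level. C and D are never fitted together.
* **Ties and degenerate inputs**: clumping breaks p-value ties by
  position then id; empty zygosity classes yield `NA` rows rather than
  errors; a threshold selecting zero variants yields a flagged zero
  score.
* **Problem sizes in the checks**: the validation script simulates
  100 000 MZ + 100 000 DZ pairs per operating point; the test suite uses
  25 000 + 25 000 for the same exercise, 200 replicates of 500 pairs for
  the LRT size check, and 100 replicates of 600 pairs for the
  BIC-selection check — sizes chosen so each check is informative at the
  stated tolerance while the whole suite stays comfortably re-runnable.
* **Multi-wave measures**: assessments from different waves are kept as
  separate `age_cohort` values; standardisation can stratify by cohort
  and sex (`standardize_by_sex(..., age_cohort)`), and pooling across
  waves is left to configuration rather than hard-coded.

## Known limitations

No sex-limitation models (DZ opposite-sex pairs are pooled with same-sex
DZ); no multivariate (>2 phenotype) models; no LD-aware shrinkage scores
or summary-statistic genetic correlations; LRT p-values at boundaries are
conservative; the logistic R² is a proxy. The PLINK-1 reader handles
hard-call SNP-major bed files only.

## A worked miniature run

```{r example, eval = FALSE}
dir <- tempfile()
make_fixtures(seed = 1, dir = dir)
pt <- read_phenotypes(file.path(dir, "phenotypes.tsv"),
                      traits = "atac_asd", diagnoses = "asd_dx")
fit <- fit_structural(pt, "atac_asd", "asd_dx", family = "AE")
summary(fit)
decompose_phenotypic_correlation(fit)
```
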