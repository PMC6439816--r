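#' Run the twin-model stage for every configured pairing
#'
#' For each trait/diagnosis pairing in the configuration this fits the
#' saturated correlations, the configured full structural model with its
#' standard reductions (`ACE` -> `AE`, `CE`, `E`; `ADE-s` -> `ADE`, `AE-s`,
#' `AE`), runs BIC/LRT model selection, and computes probandwise
#' concordances. Each pairing uses an independent seed substream derived
#' from the configuration seed.
#'
#' @param pairs a [phenotype_table()] holding all configured columns
#' @param config an [analysis_config()]
#' @param out_dir optional directory; when given, result tables are written
#'   as deterministic TSVs via [write_results()]
#' @param restarts optimiser restarts per structural fit
#' @return list of data frames: `correlations` (one row per pairing with
#'   the seven saturated correlations and CIs), `fits` (favoured-model
#'   estimates and derived correlations), `selection` (per-model BIC/LRT
#'   table), `concordances`; plus `fit_objects`
#' @export
run_twin_study <- function(pairs, config, out_dir = NULL, restarts = 3L) {
  stopifnot(inherits(config, "analysis_config"))
  if (!length(config$pairings)) stop("config has no pairings")
  reductions <- list("ACE" = c("AE", "CE", "E"),
                     "ADE-s" = c("ADE", "AE-s", "AE"))
  corr_rows <- list(); fit_rows <- list(); sel_rows <- list()
  conc_rows <- list(); fit_objects <- list()
  for (pr in config$pairings) {
    lab <- paste0(pr$trait, "~", pr$diagnosis)
    sat <- fit_saturated(pairs, pr$trait, pr$diagnosis)
    g <- function(stat, cls, col) sat[sat$statistic == stat & sat$class == cls, col]
    corr_rows[[lab]] <- data.frame(
      pairing = lab, trait = pr$trait, diagnosis = pr$diagnosis,
      rPh = g("rPh", "all", "est"), rPh_lo = g("rPh", "all", "lo"),
      rPh_hi = g("rPh", "all", "hi"),
      r_trait_MZ = g("r_trait", "MZ", "est"), r_trait_DZ = g("r_trait", "DZ", "est"),
      r_diag_MZ = g("r_diag", "MZ", "est"), r_diag_DZ = g("r_diag", "DZ", "est"),
      r_cross_MZ = g("r_cross", "MZ", "est"), r_cross_DZ = g("r_cross", "DZ", "est"))
    conc <- probandwise_concordance(pairs, pr$diagnosis)
    conc$pairing <- lab
    conc_rows[[lab]] <- conc
    if (identical(pr$family, "saturated-only")) next
    seed_p <- substream_seed(config$seed, lab)
    fits <- list()
    fits[[pr$family]] <- fit_structural(pairs, pr$trait, pr$diagnosis,
                                        family = pr$family,
                                        restarts = restarts, seed = seed_p)
    for (fam in reductions[[pr$family]]) {
      fits[[fam]] <- fit_structural(pairs, pr$trait, pr$diagnosis,
                                    family = fam, restarts = restarts,
                                    seed = seed_p)
    }
    sel <- select_model(fits, alpha = 0.05)
    sel$pairing <- lab
    sel_rows[[lab]] <- sel
    best <- fits[[sel$model[sel$favored][1]]]
    fit_objects[[lab]] <- best
    est <- coef(best); d <- best$derived
    fit_rows[[lab]] <- data.frame(
      pairing = lab, model = best$family,
      a2_trait = est[["a2.trait"]], a2_liab = est[["a2.liab"]],
      c2_trait = est[["c2.trait"]], c2_liab = est[["c2.liab"]],
      d2_trait = est[["d2.trait"]], d2_liab = est[["d2.liab"]],
      e2_trait = est[["e2.trait"]], e2_liab = est[["e2.liab"]],
      rG = d$rG, rA = d$rA, rE = d$rE, rPh_implied = d$rPh,
      genetic_share = d$genetic_share,
      loglik = best$loglik, npar = best$npar, BIC = best$BIC)
  }
  out <- list(correlations = do.call(rbind, corr_rows),
              fits = if (length(fit_rows)) do.call(rbind, fit_rows) else NULL,
              selection = if (length(sel_rows)) do.call(rbind, sel_rows) else NULL,
              concordances = do.call(rbind, conc_rows))
  for (nm in names(out)) if (!is.null(out[[nm]])) rownames(out[[nm]]) <- NULL
  if (!is.null(out_dir))
    write_results(Filter(Negate(is.null),
                         out[c("correlations", "fits", "selection", "concordances")]),
                  out_dir)
  out$fit_objects <- fit_objects
  out
}

#' Run the PRS association stage
#'
#' Harmonises the discovery summary statistics to the target panel, clumps,
#' scores at every configured threshold, derives PC covariates, and tests
#' each requested association with cluster-robust regression: full-sample
#' runs at all thresholds, plus a diagnosed-exclusion rerun at the primary
#' threshold when a test names an exclusion diagnosis. FDR adjustment is
#' applied across the primary-threshold full-sample tests as one family
#' (exclusion reruns form their own family).
#'
#' @param geno a [genotype_data()]
#' @param sumstats a [gwas_sumstats()]
#' @param data individual-level data frame with columns `id`, `pair_id`,
#'   plus outcomes, covariates and diagnosis columns
#' @param tests list of `list(outcome =, family =, exclude_dx = NULL,
#'   covariates = character())`; `covariates` names columns of `data` used
#'   in addition to the PCs
#' @param config an [analysis_config()]
#' @param mz_pairs optional MZ co-twin id matrix for [pca_covariates()]
#' @param out_dir optional output directory for the association TSV
#' @return data frame of association rows (class `gee_result` rows bound
#'   together, with `p_fdr` filled per family)
#' @export
run_prs_study <- function(geno, sumstats, data, tests, config,
                          mz_pairs = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (!length(config$thresholds)) stop("validation error: empty threshold list")
  if (!length(tests)) stop("no tests requested")
  w <- harmonize_alleles(sumstats, geno)
  w <- ld_clump(w, geno, clump_r2 = config$clump_r2, clump_kb = config$clump_kb)
  prof <- score_prs(geno, w, thresholds = config$thresholds)
  pcs <- pca_covariates(geno, k = config$n_pcs, mz_pairs = mz_pairs)
  m <- match(data$id, geno$ids)
  if (any(is.na(m))) stop("data ids missing from genotypes: ",
                          paste(head(data$id[is.na(m)]), collapse = ", "))
  pcd <- as.data.frame(pcs[m, , drop = FALSE])
  prof_m <- prof[m, , drop = FALSE]
  all_rows <- list()
  for (ti in seq_along(tests)) {
    ts <- tests[[ti]]
    fam <- if (identical(ts$family, "logistic")) "logistic" else "linear"
    cov_df <- if (length(ts$covariates)) cbind(pcd, data[ts$covariates]) else pcd
    rows <- threshold_sensitivity(prof_m, data[[ts$outcome]], cov_df,
                                  clusters = data$pair_id, family = fam,
                                  outcome_name = ts$outcome,
                                  primary_threshold = config$primary_threshold)
    rows$test <- ti
    all_rows[[length(all_rows) + 1L]] <- rows
    if (!is.null(ts$exclude_dx)) {
      keep <- is.na(data[[ts$exclude_dx]]) | data[[ts$exclude_dx]] == 0
      zcol <- paste0("z_", gsub("-", "m",
                                formatC(config$primary_threshold, format = "g")))
      ex <- gee_associate(data[[ts$outcome]][keep], prof_m[[zcol]][keep],
                          cov_df[keep, , drop = FALSE],
                          clusters = data$pair_id[keep], family = fam,
                          outcome_name = ts$outcome,
                          threshold = config$primary_threshold,
                          excluded = TRUE)
      ex$p_fdr <- NA_real_; ex$test <- ti
      all_rows[[length(all_rows) + 1L]] <- ex
    }
  }
  out <- do.call(rbind, all_rows)
  prim_full <- which(out$threshold == config$primary_threshold & !out$excluded)
  out$p_fdr[prim_full] <- fdr_adjust(out$p[prim_full])
  prim_ex <- which(out$excluded)
  if (length(prim_ex)) out$p_fdr[prim_ex] <- fdr_adjust(out$p[prim_ex])
  rownames(out) <- NULL
  if (!is.null(out_dir)) write_results(list(prs_associations = out), out_dir)
  out
}

#' Generate the small self-contained fixture bundle
#'
#' Writes a complete miniature study to `dir`: 500 twin pairs with one
#' trait and one (ASD-like, ~1% prevalence) diagnosis, a 200-variant
#' genotype panel as PLINK-1 bed/bim/fam, a discovery summary-statistics
#' TSV, a YAML configuration, and a manifest with the md5 digest of every
#' file. Bit-identical for a given seed.
#'
#' @param seed master seed
#' @param dir output directory
#' @return named character vector of md5 digests, invisibly
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- twin_spec(a2 = c(0.74, 0.81), rA = 0.48, rE = 0.353,
                  tau = c(M = qnorm(0.991), F = qnorm(0.991)),
                  n_pairs = c(MZM = 90, DZM = 90, MZF = 85, DZF = 85, DZOS = 150),
                  missing_rate = c(trait = 0.05, diagnosis = 0),
                  seed = substream_seed(seed, "fix_twin"))
  pt <- simulate_twin_pairs(sp, trait = "atac_asd", diagnosis = "asd_dx")
  ps <- polygenic_spec(m_variants = 200L, n_causal = 30L, block_size = 8L,
                       block_r = 0.4, effect_sd = 0.08, n_discovery = 20000L,
                       h2_score = 0.1, seed = substream_seed(seed, "fix_geno"))
  geno <- simulate_genotypes(ps, pt)
  # a genetically driven outcome so score-trait associations exist by
  # construction in the bundle
  ph <- attach_genetic_phenotype(geno, attr(geno, "truth"), ps)
  idx <- match(paste0(pt$pair_id, "_", pt$twin_order), ph$id)
  pt$poly_trait <- ph$outcome[idx]
  pt <- phenotype_table(as.data.frame(pt),
                        traits = c("atac_asd", "poly_trait"),
                        diagnoses = "asd_dx")
  write_phenotypes(pt, file.path(dir, "phenotypes.tsv"))
  sexes <- rep(pt$sex, 1)[match(geno$ids, paste0(pt$pair_id, "_", pt$twin_order))]
  write_plink1(geno, file.path(dir, "geno"), sex = sexes)
  ss <- simulate_discovery_sumstats(ps, attr(geno, "truth"))
  write_summary_stats(ss, file.path(dir, "sumstats.tsv"))
  cfg <- analysis_config(
    pairings = list(list(trait = "atac_asd", diagnosis = "asd_dx",
                         family = "ACE")),
    seed = seed)
  write_config(cfg, file.path(dir, "config.yaml"))
  files <- file.path(dir, c("phenotypes.tsv", "geno.bed", "geno.bim",
                            "geno.fam", "sumstats.tsv", "config.yaml"))
  digests <- tools::md5sum(files)
  names(digests) <- basename(files)
  yaml::write_yaml(list(seed = seed, digests = as.list(digests)),
                   file.path(dir, "manifest.yaml"))
  invisible(digests)
}
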