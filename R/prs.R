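#' Harmonise summary-statistic alleles to the target genotypes
#'
#' Matches variants by id and aligns the effect allele to the target panel's
#' `allele1`: when the discovery effect allele equals the target `allele2`
#' (and the other allele equals `allele1`) the effect-size sign is flipped;
#' strand-ambiguous variants (A/T, C/G) and allele mismatches are dropped.
#' Counts of flipped/ambiguous/mismatched/absent variants are attached as
#' attribute `counts` and reported via `message()`.
#'
#' @param sumstats a [gwas_sumstats()]
#' @param geno a [genotype_data()]
#' @return data frame `id, col, chrom, pos, beta, p` (`col` indexes the
#'   genotype dosage column), class `prs_weights`
#' @export
harmonize_alleles <- function(sumstats, geno) {
  v <- geno$variants
  idx <- match(sumstats$id, v$id)
  present <- !is.na(idx)
  counts <- c(matched = 0L, flipped = 0L, ambiguous = 0L,
              mismatch = 0L, absent = sum(!present))
  ss <- sumstats[present, ]
  gv <- v[idx[present], ]
  flip_pair <- function(a) chartr("ACGT", "TGCA", a)
  ambiguous <- ss$effect_allele == flip_pair(ss$other_allele)
  straight <- ss$effect_allele == gv$allele1 & ss$other_allele == gv$allele2
  flipped <- ss$effect_allele == gv$allele2 & ss$other_allele == gv$allele1
  keep <- !ambiguous & (straight | flipped)
  counts["ambiguous"] <- sum(ambiguous)
  counts["mismatch"] <- sum(!ambiguous & !straight & !flipped)
  counts["flipped"] <- sum(!ambiguous & flipped)
  counts["matched"] <- sum(keep)
  if (!any(keep)) stop("no variants could be harmonised (zero overlap)")
  out <- data.frame(id = ss$id[keep],
                    col = match(ss$id[keep], v$id),
                    chrom = gv$chrom[keep], pos = gv$pos[keep],
                    beta = ifelse(flipped[keep], -ss$beta[keep], ss$beta[keep]),
                    p = ss$p[keep], stringsAsFactors = FALSE)
  message("harmonize_alleles: ", paste(names(counts), counts, sep = "=",
                                       collapse = ", "))
  attr(out, "counts") <- counts
  class(out) <- c("prs_weights", "data.frame")
  out
}

#' Greedy LD clumping of summary statistics
#'
#' Standard index-variant selection: sort by ascending p (ties broken by
#' position, then id), take the best remaining variant as an index, remove
#' all remaining variants on the same chromosome within the window whose
#' dosage r-squared with the index exceeds the threshold, and repeat.
#' Deterministic and invariant to input row order.
#'
#' @param weights a harmonised weight table ([harmonize_alleles()])
#' @param geno the reference [genotype_data()] for LD
#' @param clump_r2 r-squared removal threshold
#' @param clump_kb window half-width in kilobases
#' @param p_ceiling variants with larger p are never indexed (default 1)
#' @return the subset of `weights` rows kept as index variants
#' @export
ld_clump <- function(weights, geno, clump_r2 = 0.1, clump_kb = 250,
                     p_ceiling = 1) {
  stopifnot(clump_r2 > 0, clump_r2 <= 1, clump_kb > 0)
  w <- weights[weights$p <= p_ceiling, , drop = FALSE]
  ord <- order(w$p, w$pos, w$id)
  w <- w[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(w))
  keep <- logical(nrow(w))
  window <- clump_kb * 1000
  for (i in seq_len(nrow(w))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & w$chrom == w$chrom[i] &
                  abs(w$pos - w$pos[i]) <= window)
    if (!length(cand)) next
    x <- geno$dosage[, w$col[i]]
    r2 <- vapply(cand, function(j) {
      r <- suppressWarnings(cor(x, geno$dosage[, w$col[j]],
                                use = "pairwise.complete.obs"))
      if (is.na(r)) 0 else r^2
    }, 0)
    alive[cand[r2 > clump_r2]] <- FALSE
  }
  out <- w[keep, , drop = FALSE]
  out[order(out$pos), , drop = FALSE]
}

#' Polygenic risk scores at a grid of p-value thresholds
#'
#' For each threshold, sums effect-allele dosages weighted by the
#' (harmonised, clumped) effect sizes over variants with discovery
#' `p < threshold`; missing dosages are mean-imputed as twice the
#' effect-allele frequency computed in the target sample; scores are then
#' z-standardised (denominator `n - 1`). A threshold selecting zero
#' variants yields a zero column, flagged in attribute `empty_thresholds`.
#'
#' @param geno a [genotype_data()]
#' @param weights clumped [harmonize_alleles()] output
#' @param thresholds ascending p-value grid
#' @return object of class `prs_profile`: data frame with `id`, one raw and
#'   one z column per threshold (`raw_<t>`, `z_<t>`), and attribute
#'   `n_variants` (variants used per threshold)
#' @export
score_prs <- function(geno, weights, thresholds = 0.5) {
  thr_lab <- function(t) gsub("-", "m", formatC(t, format = "g"))
  d <- geno$dosage[, weights$col, drop = FALSE]
  freq <- colMeans(d, na.rm = TRUE) / 2
  for (j in seq_len(ncol(d))) {
    mj <- is.na(d[, j])
    if (any(mj)) d[mj, j] <- 2 * freq[j]
  }
  out <- data.frame(id = geno$ids, stringsAsFactors = FALSE)
  nv <- integer(length(thresholds))
  empty <- numeric(0)
  for (k in seq_along(thresholds)) {
    sel <- weights$p < thresholds[k]
    nv[k] <- sum(sel)
    raw <- if (nv[k] > 0) as.vector(d[, sel, drop = FALSE] %*% weights$beta[sel])
           else rep(0, nrow(d))
    z <- if (nv[k] > 0 && sd(raw) > 0) (raw - mean(raw)) / sd(raw) else rep(0, nrow(d))
    if (nv[k] == 0) empty <- c(empty, thresholds[k])
    out[[paste0("raw_", thr_lab(thresholds[k]))]] <- raw
    out[[paste0("z_", thr_lab(thresholds[k]))]] <- z
  }
  if (length(empty))
    warning("threshold(s) ", paste(empty, collapse = ", "), " selected 0 variants")
  attr(out, "n_variants") <- setNames(nv, thr_lab(thresholds))
  attr(out, "thresholds") <- thresholds
  class(out) <- c("prs_profile", "data.frame")
  out
}

#' Principal-component stratification covariates
#'
#' LD-prunes (greedy, r-squared cut within a sliding variant window) and
#' MAF-filters the panel, scales dosages by allele frequency
#' (`(x - 2p) / sqrt(2p(1-p))`), and extracts the top `k` principal
#' components. Only one member of each MZ pair enters the decomposition
#' (identical genotypes would otherwise distort the eigenstructure); the
#' co-twin is assigned its sibling's PC coordinates afterwards. The sign
#' convention makes the largest-magnitude loading of each PC positive.
#'
#' @param geno a [genotype_data()]
#' @param k number of components
#' @param mz_pairs optional 2-column character matrix of MZ co-twin ids
#' @param maf_min minor-allele-frequency filter
#' @param prune_window,prune_step,prune_r2 LD-pruning parameters (variant
#'   counts, as in common GWAS practice)
#' @return numeric matrix (individuals x k) with rownames = ids
#' @export
pca_covariates <- function(geno, k = 10L, mz_pairs = NULL, maf_min = 0.05,
                           prune_window = 50L, prune_step = 5L, prune_r2 = 0.2) {
  d <- geno$dosage
  freq <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  keep_v <- which(maf >= maf_min)
  keep_v <- .ld_prune(d, keep_v, prune_window, prune_step, prune_r2)
  if (length(keep_v) < k) stop("k exceeds the number of variants after pruning")
  rows <- seq_along(geno$ids)
  drop_ids <- if (!is.null(mz_pairs)) mz_pairs[, 2] else character(0)
  use_r <- rows[!geno$ids %in% drop_ids]
  if (length(use_r) < k) stop("k exceeds the number of individuals")
  X <- d[use_r, keep_v, drop = FALSE]
  p <- colMeans(X, na.rm = TRUE) / 2
  X <- sweep(X, 2, 2 * p)
  X <- sweep(X, 2, sqrt(pmax(2 * p * (1 - p), 1e-8)), "/")
  X[is.na(X)] <- 0
  pc <- prcomp(X, center = FALSE, scale. = FALSE, rank. = k)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  out <- matrix(NA_real_, length(rows), k,
                dimnames = list(geno$ids, paste0("PC", seq_len(k))))
  out[use_r, ] <- scores
  if (!is.null(mz_pairs)) {
    i2 <- match(mz_pairs[, 2], geno$ids)
    i1 <- match(mz_pairs[, 1], geno$ids)
    ok <- !is.na(i1) & !is.na(i2)
    out[i2[ok], ] <- out[i1[ok], ]
  }
  out
}

# greedy sliding-window LD pruning over candidate columns
.ld_prune <- function(d, cand, window, step, r2max) {
  keep <- rep(TRUE, length(cand))
  i <- 1L
  while (i <= length(cand)) {
    win <- i:min(i + window - 1L, length(cand))
    act <- win[keep[win]]
    if (length(act) > 1) {
      cm <- suppressWarnings(cor(d[, cand[act], drop = FALSE],
                                 use = "pairwise.complete.obs"))
      cm[is.na(cm)] <- 0
      for (a in seq_along(act)) {
        if (!keep[act[a]]) next
        hi <- which(cm[a, ]^2 > r2max)
        hi <- hi[hi > a & keep[act[hi]]]
        keep[act[hi]] <- FALSE
      }
    }
    i <- i + step
  }
  cand[keep]
}
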