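#' Saturated twin correlations for one trait/diagnosis pairing
#'
#' Estimates the descriptive correlation set reported ahead of structural
#' modelling: the phenotypic trait-diagnosis correlation (polyserial, pooled
#' across zygosity classes), and per zygosity class (MZ pooled across sexes;
#' DZ pooling same-sex and opposite-sex pairs) the cross-twin trait
#' correlation (Pearson on double-entered pairs, enforcing equal means and
#' variances across twin order), the cross-twin diagnosis correlation
#' (tetrachoric with the threshold pooled across classes), and the
#' cross-twin cross-trait correlation (polyserial on double-entered
#' trait/co-twin-diagnosis pairs).
#'
#' Confidence intervals are normal-theory on the Fisher-z scale using the
#' number of contributing pairs (double-entry is not double-counted).
#'
#' @param pairs a [phenotype_table()]
#' @param trait,diagnosis column names
#' @param conf_level confidence level for the intervals
#' @param min_pairs classes with fewer pairs are still fitted, with a warning
#' @return object of class `twin_saturated`: a data frame with one row per
#'   statistic (`rPh`, and `r_trait`, `r_diag`, `r_cross` for MZ and DZ),
#'   columns `est`, `lo`, `hi`, `n_pairs`, `boundary`
#' @export
fit_saturated <- function(pairs, trait, diagnosis, conf_level = 0.95,
                          min_pairs = 30L) {
  stopifnot(inherits(pairs, "phenotype_table"))
  pt <- pairs
  pt[[trait]] <- standardize_by_sex(pt[[trait]], pt$sex)
  w <- pair_wide(pt, c(trait, diagnosis))
  zclass <- ifelse(w$zygosity %in% c("MZM", "MZF"), "MZ", "DZ")
  zcrit <- qnorm(1 - (1 - conf_level) / 2)

  fz_ci <- function(r, n) {
    if (is.na(r) || n < 4 || abs(r) >= 1) return(c(NA_real_, NA_real_))
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    tanh(c(z - zcrit * se, z + zcrit * se))
  }
  row <- function(stat, class, est, n, boundary = FALSE) {
    ci <- fz_ci(est, n)
    data.frame(statistic = stat, class = class, est = est,
               lo = ci[1], hi = ci[2], n_pairs = n, boundary = boundary)
  }

  # phenotypic correlation, constrained equal across classes: pool everyone
  ps <- tryCatch(polyserial_corr(pt[[trait]], pt[[diagnosis]]),
                 error = function(e) list(rho = NA_real_, boundary = FALSE))
  n_ph <- sum(complete.cases(pt[[trait]], pt[[diagnosis]]))
  out <- row("rPh", "all", ps$rho, n_ph, isTRUE(ps$boundary))

  t1 <- w[[paste0(trait, ".1")]]; t2 <- w[[paste0(trait, ".2")]]
  y1 <- w[[paste0(diagnosis, ".1")]]; y2 <- w[[paste0(diagnosis, ".2")]]

  for (z in c("MZ", "DZ")) {
    sel <- zclass == z
    if (!any(sel)) {
      for (stat in c("r_trait", "r_diag", "r_cross"))
        out <- rbind(out, row(stat, z, NA_real_, 0L))
      next
    }
    if (sum(sel) < min_pairs)
      warning("zygosity class ", z, " has only ", sum(sel), " pairs")
    okt <- sel & !is.na(t1) & !is.na(t2)
    r_tr <- if (sum(okt) >= 3)
      cor(c(t1[okt], t2[okt]), c(t2[okt], t1[okt])) else NA_real_
    out <- rbind(out, row("r_trait", z, r_tr, sum(okt)))

    oky <- sel & !is.na(y1) & !is.na(y2)
    if (sum(oky) >= 3 && length(unique(c(y1[oky], y2[oky]))) == 2) {
      tab <- table(factor(c(y1[oky], y2[oky]), 0:1),
                   factor(c(y2[oky], y1[oky]), 0:1)) / 2
      tc <- tryCatch(tetrachoric_corr(tab), warning = function(wn) {
        res <- suppressWarnings(tetrachoric_corr(tab)); res$warned <- TRUE; res
      })
      out <- rbind(out, row("r_diag", z, tc$rho, sum(oky), isTRUE(tc$boundary)))
    } else out <- rbind(out, row("r_diag", z, NA_real_, sum(oky)))

    okx <- sel & ((!is.na(t1) & !is.na(y2)) | (!is.na(t2) & !is.na(y1)))
    xs <- c(t1[sel], t2[sel]); ys <- c(y2[sel], y1[sel])
    r_x <- tryCatch(polyserial_corr(xs, ys)$rho, error = function(e) NA_real_)
    out <- rbind(out, row("r_cross", z, r_x, sum(okx)))
  }
  rownames(out) <- NULL
  structure(out, class = c("twin_saturated", "data.frame"),
            trait = trait, diagnosis = diagnosis)
}

#' @export
print.twin_saturated <- function(x, ...) {
  cat("Saturated twin correlations:", attr(x, "trait"), "~",
      attr(x, "diagnosis"), "\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Probandwise concordance of a diagnosis by zygosity
#'
#' `2C / (2C + D)` where `C` counts pairs with both twins affected and `D`
#' pairs with exactly one affected (only pairs with both diagnoses observed
#' contribute). Undefined (reported `NA`) when there are no affected pairs.
#'
#' @param pairs a [phenotype_table()]
#' @param diagnosis diagnosis column name
#' @return data frame with one row per zygosity class (`MZ`, `DZ`):
#'   `n_concordant`, `n_discordant`, `concordance`
#' @export
probandwise_concordance <- function(pairs, diagnosis) {
  stopifnot(inherits(pairs, "phenotype_table"))
  if (!diagnosis %in% names(pairs)) stop("no such diagnosis column: ", diagnosis)
  w <- pair_wide(pairs, diagnosis)
  zclass <- ifelse(w$zygosity %in% c("MZM", "MZF"), "MZ", "DZ")
  y1 <- w[[paste0(diagnosis, ".1")]]; y2 <- w[[paste0(diagnosis, ".2")]]
  ok <- !is.na(y1) & !is.na(y2)
  res <- lapply(c("MZ", "DZ"), function(z) {
    sel <- ok & zclass == z
    C <- sum(y1[sel] == 1 & y2[sel] == 1)
    D <- sum(y1[sel] + y2[sel] == 1)
    data.frame(zygosity = z, n_concordant = C, n_discordant = D,
               concordance = if (C + D == 0) NA_real_ else 2 * C / (2 * C + D))
  })
  do.call(rbind, res)
}
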