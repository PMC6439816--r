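#' @export
print.twin_fit <- function(x, ...) {
  cat("Bivariate liability-threshold twin model (", x$family, ")\n", sep = "")
  cat("  pairing: ", x$trait, " (continuous) ~ ", x$diagnosis,
      " (liability)\n", sep = "")
  cat(sprintf("  logLik %.3f on %d free parameters, N = %d pairs, BIC %.1f\n",
              x$loglik, x$npar, x$N, x$BIC))
  d <- x$derived
  cat(sprintf("  rG = %.3f  rE = %.3f  rPh(implied) = %.3f  genetic share %.1f%%\n",
              d$rG, d$rE, d$rPh, 100 * d$genetic_share))
  if (length(x$boundary))
    cat("  boundary estimates:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.twin_fit <- function(object, ...) {
  est <- object$estimates
  keep <- !(grepl("^[cd]2", names(est)) & est == 0) &
    !(names(est) %in% c("rC", "rD") & est == 0) &
    !(grepl("^s\\.", names(est)) & est == 0)
  out <- list(fit = object, estimates = est[keep],
              derived = object$derived,
              shares = object$derived$shares)
  class(out) <- "summary.twin_fit"
  out
}

#' @export
print.summary.twin_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter estimates:\n")
  print(round(x$estimates, 4))
  cat("\nDecomposition of the phenotypic correlation (shares):\n")
  print(round(x$shares[!is.na(x$shares) & x$shares != 0], 4))
  invisible(x)
}

#' @export
coef.twin_fit <- function(object, ...) object$estimates

#' @export
logLik.twin_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$N,
            class = "logLik")
}

#' Profile-likelihood confidence intervals for twin-model correlations
#'
#' Profiles the factor correlations (`rA`, `rE`, ...) by refitting with the
#' target parameter fixed on a bracketing search until the likelihood-ratio
#' statistic crosses `qchisq(level, 1)` (3.84 at 95%). Estimates at a
#' boundary return `NA` on that side.
#'
#' @param object a `twin_fit`
#' @param parm parameters to profile (default `c("rA", "rE")`)
#' @param level confidence level
#' @param ... unused
#' @return matrix with columns `lo`, `hi`
#' @export
confint.twin_fit <- function(object, parm = c("rA", "rE"), level = 0.95, ...) {
  crit <- qchisq(level, 1)
  target <- object$loglik - crit / 2
  refit_ll <- function(nm, value) {
    fx <- object$fixed
    fx[[nm]] <- value
    f <- tryCatch(
      fit_structural(.rebuild_table(object), object$trait, object$diagnosis,
                     family = object$family, fixed = fx,
                     standardize = object$standardize, restarts = 1L,
                     seed = object$seed),
      error = function(e) NULL)
    if (is.null(f)) -Inf else f$loglik
  }
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lo", "hi")))
  for (nm in parm) {
    hat <- object$estimates[[nm]]
    if (is.null(hat) || is.na(hat)) next
    for (side in c(-1, 1)) {
      lo <- hat; hi <- side  # search toward the boundary
      if (abs(hat - side) < 1e-3) { bound <- NA_real_ }
      else {
        f_hi <- refit_ll(nm, side * 0.999)
        if (f_hi > target) { bound <- side }
        else {
          for (it in 1:25) {
            mid <- (lo + hi) / 2
            if (refit_ll(nm, mid) > target) lo <- mid else hi <- mid
            if (abs(hi - lo) < 5e-4) break
          }
          bound <- (lo + hi) / 2
        }
      }
      out[nm, if (side < 0) "lo" else "hi"] <- bound
    }
  }
  out
}

# reconstruct a minimal phenotype table from the cached fit data (used by
# profiling so confint needs no access to the original file)
.rebuild_table <- function(fit) {
  rows <- list()
  pid <- 0L
  for (z in names(fit$data)) {
    d <- fit$data[[z]]
    sex1 <- c("M", "F")[d$i1]; sex2 <- c("M", "F")[d$i2]
    zyg <- if (z == "MZ") ifelse(sex1 == "M", "MZM", "MZF")
           else ifelse(sex1 != sex2, "DZOS", ifelse(sex1 == "M", "DZM", "DZF"))
    ids <- sprintf("P%07d", pid + seq_len(d$n)); pid <- pid + d$n
    rows[[z]] <- data.frame(
      pair_id = rep(ids, each = 2), twin_order = rep(1:2, d$n),
      zygosity = rep(zyg, each = 2),
      sex = as.vector(rbind(sex1, sex2)), age_cohort = 9L,
      tr = as.vector(rbind(d$t1, d$t2)),
      dx = as.vector(rbind(d$y1, d$y2)))
  }
  df <- do.call(rbind, rows)
  names(df)[names(df) == "tr"] <- fit$trait
  names(df)[names(df) == "dx"] <- fit$diagnosis
  phenotype_table(df, traits = fit$trait, diagnoses = fit$diagnosis)
}

#' Simulate phenotype tables from a fitted twin model
#'
#' Parametric simulation: draws new twin pairs from the fitted parameters
#' with the same zygosity-class sizes and sex mix as the fitted data.
#'
#' @param object a `twin_fit`
#' @param nsim number of tables
#' @param seed master seed
#' @param ... unused
#' @return list of [phenotype_table()] objects
#' @export
simulate.twin_fit <- function(object, nsim = 1, seed = 1L, ...) {
  cnt <- c(MZM = 0, DZM = 0, MZF = 0, DZF = 0, DZOS = 0)
  for (z in names(object$data)) {
    d <- object$data[[z]]
    sex1 <- c("M", "F")[d$i1]; sex2 <- c("M", "F")[d$i2]
    if (z == "MZ") {
      cnt["MZM"] <- cnt["MZM"] + sum(sex1 == "M")
      cnt["MZF"] <- cnt["MZF"] + sum(sex1 == "F")
    } else {
      cnt["DZOS"] <- cnt["DZOS"] + sum(sex1 != sex2)
      cnt["DZM"] <- cnt["DZM"] + sum(sex1 == "M" & sex2 == "M")
      cnt["DZF"] <- cnt["DZF"] + sum(sex1 == "F" & sex2 == "F")
    }
  }
  lapply(seq_len(nsim), function(i) {
    sp <- object$spec
    sp$n_pairs <- cnt
    sp$seed <- substream_seed(seed, paste0("simfit", i))
    simulate_twin_pairs(sp, trait = object$trait, diagnosis = object$diagnosis)
  })
}

#' Decompose the model-implied phenotypic correlation
#'
#' Splits the fitted model's implied trait-liability correlation into the
#' contributions of the active variance components. Without sibling
#' interaction this is the textbook sum `rPh = sum_k r_k *
#' sqrt(v_k,trait * v_k,liab)`; with interaction each latent component is
#' propagated separately through the reciprocal-path transform, which is
#' exact by linearity. Shares sum to 1 over active components.
#'
#' @param fit a `twin_fit`
#' @return list with `rPh`, per-component `terms` and `shares`, and
#'   `genetic_share` (A + D combined)
#' @export
decompose_phenotypic_correlation <- function(fit) {
  stopifnot(inherits(fit, "twin_fit"))
  d <- fit$derived
  if (is.na(d$shares[1]))
    warning("phenotypic correlation ~ 0; shares undefined")
  active <- d$shares[!vapply(d$shares, function(x) isTRUE(x == 0), TRUE)]
  list(rPh = d$rPh, terms = d$shares * d$rPh, shares = d$shares,
       genetic_share = d$genetic_share)
}
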