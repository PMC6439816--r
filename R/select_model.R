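#' Likelihood-ratio test between nested twin-model fits
#'
#' Chi-squared test on `-2 * (logLik_reduced - logLik_full)` with degrees of
#' freedom equal to the difference in free-parameter counts. The reduced
#' model must be nested in the full one (same family up to dropped
#' components/fixed parameters, fewer free parameters); a reduced fit with a
#' noticeably higher likelihood than the full fit is rejected as non-nested
#' or non-converged.
#'
#' Boundary caveat: when the constrained parameter sits on the edge of its
#' space (a variance proportion at 0) the chi-squared reference is
#' conservative; p-values are reported untransformed, without a mixture
#' correction.
#'
#' @param full,reduced `twin_fit` objects
#' @return list with `statistic`, `df`, `p`
#' @export
lrt_twin <- function(full, reduced) {
  stopifnot(inherits(full, "twin_fit"), inherits(reduced, "twin_fit"))
  df <- full$npar - reduced$npar
  if (df <= 0) stop("models are not nested: reduced must have fewer free parameters")
  stat <- -2 * (reduced$loglik - full$loglik)
  if (stat < -1e-4) {
    full <- .refit_from(full, reduced)
    stat <- -2 * (reduced$loglik - full$loglik)
  }
  if (stat < -1e-4)
    stop("reduced model has higher likelihood than full: not nested or full fit not converged")
  stat <- max(stat, 0)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# A full model whose likelihood falls below a nested reduction has not
# converged; refit it warm-started from the reduced solution (standard
# practice when walking a model-reduction chain) and keep the better fit.
.refit_from <- function(full, reduced) {
  est <- as.list(coef(reduced))
  st <- list()
  for (nm in names(est)) {
    v <- est[[nm]]
    if (grepl("^[acd]2\\.", nm)) st[[nm]] <- min(max(v, 0.02), 0.95)
    else if (grepl("^r[ACDE]$|^s\\.", nm)) st[[nm]] <- min(max(v, -0.95), 0.95)
    else if (grepl("^tau", nm)) st[[nm]] <- v
  }
  refit <- tryCatch({
    fit_structural(.rebuild_table(full), full$trait, full$diagnosis,
                   family = full$family, fixed = full$fixed,
                   standardize = full$standardize, restarts = 1L,
                   seed = full$seed, start = st)
  }, error = function(e) NULL)
  if (!is.null(refit) && refit$loglik > full$loglik) refit else full
}

#' Model-selection report over a set of twin-model fits
#'
#' Builds the comparison table used to pick the reported model: BIC for
#' every fit, and a likelihood-ratio test of each reduced model against the
#' full model (the first element, by convention the ACE or ADE-s fit). The
#' favoured model is the lowest-BIC model among the full model and all
#' reductions whose fit does not deteriorate significantly (LRT p >=
#' `alpha`); ties go to the model with fewer parameters.
#'
#' @param fits named list of `twin_fit` objects, full model first
#' @param alpha LRT significance level for "deteriorates significantly"
#' @return data frame of class `twin_model_selection` with columns `model`,
#'   `npar`, `loglik`, `BIC`, `lrt_stat`, `lrt_df`, `lrt_p`, `favored`
#' @export
select_model <- function(fits, alpha = 0.05) {
  stopifnot(is.list(fits), length(fits) >= 1, !is.null(names(fits)))
  full <- fits[[1]]
  if (length(fits) > 1 && !is.null(full$data)) {
    lls <- vapply(fits[-1], `[[`, 0, "loglik")
    best_red <- fits[-1][[which.max(lls)]]
    if (best_red$loglik > full$loglik + 1e-6) {
      full <- .refit_from(full, best_red)
      fits[[1]] <- full
    }
  }
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (i == 1) {
      lr <- list(statistic = NA_real_, df = NA_integer_, p = NA_real_)
    } else lr <- lrt_twin(full, f)
    data.frame(model = names(fits)[i], npar = f$npar, loglik = f$loglik,
               BIC = f$BIC, lrt_stat = lr$statistic, lrt_df = lr$df,
               lrt_p = lr$p)
  })
  tab <- do.call(rbind, rows)
  candidate <- is.na(tab$lrt_p) | tab$lrt_p >= alpha
  cand <- tab[candidate, ]
  pick <- cand$model[order(cand$BIC, cand$npar)][1]
  tab$favored <- tab$model == pick
  structure(tab, class = c("twin_model_selection", "data.frame"))
}

#' @export
print.twin_model_selection <- function(x, ...) {
  cat("Twin-model selection (full model first; LRT vs full)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
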