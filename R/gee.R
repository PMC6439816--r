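#' PRS-outcome association with cluster-robust standard errors
#'
#' Estimating-equations regression with an independence working
#' correlation: point estimates are the ordinary GLM estimates (linear or
#' logistic), and the variance is the cluster sandwich
#' `B (sum_c s_c s_c^T) B` with `B` the unscaled bread `(X'WX)^-1` and
#' `s_c` the summed score contributions `x_i (y_i - mu_i)` of cluster `c`
#' (twin pairs share a cluster). With singleton clusters this reduces to
#' the HC0 heteroskedasticity-consistent sandwich.
#'
#' Effect sizes are per unit of the predictor — per SD when the PRS is
#' z-standardised. For logistic outcomes the odds ratio `exp(beta)` is
#' reported with `exp(beta +/- 1.96 se)` CIs. Variance explained is the
#' increment over the covariate-only model: Delta R-squared for linear
#' outcomes and, for logistic ones, the increment in the squared
#' correlation between outcome and fitted probability (a documented proxy).
#'
#' @param outcome numeric (linear) or 0/1 (logistic) response
#' @param prs predictor of interest (standardised score)
#' @param covariates data frame or matrix of adjustment covariates (PCs,
#'   sex, age); may be `NULL`
#' @param clusters cluster labels (pair ids), one per observation
#' @param family `"linear"` or `"logistic"`
#' @param outcome_name label carried into the result row
#' @param threshold,excluded bookkeeping columns for the result row
#' @return one-row data frame of class `gee_result`: `outcome, family, n,
#'   n_clusters, beta, se, z, p, OR, or_lo, or_hi, r2, threshold, excluded`
#' @export
gee_associate <- function(outcome, prs, covariates = NULL, clusters,
                          family = c("linear", "logistic"),
                          outcome_name = "outcome", threshold = NA_real_,
                          excluded = FALSE) {
  family <- match.arg(family)
  X <- data.frame(prs = prs)
  if (!is.null(covariates)) X <- cbind(X, as.data.frame(covariates))
  df <- cbind(data.frame(.y = outcome, .cl = as.character(clusters)), X)
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  npar <- ncol(X) + 1L
  if (n < 10 * npar)
    stop("too few complete cases (", n, ") for ", npar, " parameters")
  fam <- if (family == "linear") gaussian() else binomial()
  fml <- .y ~ .
  fit <- glm(fml, data = df[c(".y", names(X))], family = fam)
  if (family == "logistic" && any(abs(coef(fit)) > 15, na.rm = TRUE))
    stop("apparent separation in logistic fit: |coefficient| > 15 for ",
         paste(names(coef(fit))[abs(coef(fit)) > 15], collapse = ", "))
  V <- .cluster_sandwich(fit, df$.cl)
  b <- coef(fit)["prs"]
  se <- sqrt(V["prs", "prs"])
  z <- b / se
  p <- 2 * pnorm(-abs(z))
  # incremental variance explained by the PRS over the covariates
  fit0 <- glm(.y ~ ., data = df[c(".y", setdiff(names(X), "prs"))], family = fam)
  if (family == "linear") {
    r2 <- 1 - sum(residuals(fit)^2) / sum((df$.y - mean(df$.y))^2)
    r20 <- 1 - sum(residuals(fit0)^2) / sum((df$.y - mean(df$.y))^2)
  } else {
    r2 <- suppressWarnings(cor(df$.y, fitted(fit)))^2
    r20 <- suppressWarnings(cor(df$.y, fitted(fit0)))^2
    if (is.na(r20)) r20 <- 0
  }
  out <- data.frame(outcome = outcome_name, family = family, n = n,
                    n_clusters = length(unique(df$.cl)),
                    beta = unname(b), se = unname(se), z = unname(z),
                    p = unname(p),
                    OR = if (family == "logistic") exp(unname(b)) else NA_real_,
                    or_lo = if (family == "logistic") exp(unname(b) - 1.96 * unname(se)) else NA_real_,
                    or_hi = if (family == "logistic") exp(unname(b) + 1.96 * unname(se)) else NA_real_,
                    r2 = max(r2 - r20, 0), threshold = threshold,
                    excluded = excluded, stringsAsFactors = FALSE)
  class(out) <- c("gee_result", "data.frame")
  out
}

# cluster-robust sandwich for a fitted glm (canonical links):
# score s_i = x_i (y_i - mu_i); bread = unscaled (X'WX)^-1
.cluster_sandwich <- function(fit, cl) {
  X <- model.matrix(fit)
  r <- fit$y - fitted(fit)
  S <- X * r
  Sc <- rowsum(S, cl)
  meat <- crossprod(as.matrix(Sc))
  bread <- summary(fit)$cov.unscaled
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Drop diagnosed individuals
#'
#' Removes individuals (not whole pairs) carrying the relevant diagnosis,
#' reproducing the sensitivity rerun that checks whether an association is
#' driven by clinically recognised cases. The number removed is reported.
#'
#' @param data individual-level data frame
#' @param diagnosis name of a 0/1 column in `data`
#' @return filtered data frame with attribute `n_excluded`
#' @export
exclude_diagnosed <- function(data, diagnosis) {
  if (!diagnosis %in% names(data)) stop("no such diagnosis column: ", diagnosis)
  dx <- data[[diagnosis]]
  drop <- !is.na(dx) & dx == 1
  message("exclude_diagnosed: removed ", sum(drop), " of ", nrow(data),
          " individuals")
  out <- data[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1), as
#' implemented by `p.adjust(method = "fdr")`.
#'
#' @param pvalues numeric vector in `[0, 1]`
#' @return adjusted p-values, same order as the input
#' @export
fdr_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "fdr")
}

#' PRS association across all selection thresholds
#'
#' Reruns [gee_associate()] for the score at every threshold of a
#' [score_prs()] profile. FDR adjustment is applied within the
#' primary-threshold family (`p_fdr` is `NA` for other thresholds, which
#' form their own reporting families).
#'
#' @param profile a [score_prs()] profile
#' @param outcome,covariates,clusters,family,outcome_name as in
#'   [gee_associate()]
#' @param primary_threshold threshold whose tests form the FDR family
#' @return data frame with one `gee_result` row per threshold
#' @export
threshold_sensitivity <- function(profile, outcome, covariates = NULL,
                                  clusters, family = "linear",
                                  outcome_name = "outcome",
                                  primary_threshold = 0.5) {
  thresholds <- attr(profile, "thresholds")
  if (!length(thresholds)) stop("profile carries no thresholds")
  zcols <- grep("^z_", names(profile), value = TRUE)
  rows <- lapply(seq_along(thresholds), function(k) {
    gee_associate(outcome, profile[[zcols[k]]], covariates, clusters,
                  family = family, outcome_name = outcome_name,
                  threshold = thresholds[k])
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  prim <- which(out$threshold == primary_threshold)
  out$p_fdr[prim] <- fdr_adjust(out$p[prim])
  out
}
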