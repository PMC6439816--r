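#' Standardise a continuous measure within sex strata
#'
#' Centres and scales to unit SD (denominator `n - 1`) within each sex (and,
#' optionally, each age-cohort-by-sex) stratum. Missing values are preserved.
#' Idempotent to numerical precision.
#'
#' @param values numeric vector, may contain `NA`
#' @param sex stratum labels, same length
#' @param age_cohort optional second stratification factor
#' @return standardised numeric vector
#' @export
standardize_by_sex <- function(values, sex, age_cohort = NULL) {
  stopifnot(length(values) == length(sex))
  strata <- if (is.null(age_cohort)) as.character(sex)
            else paste(sex, age_cohort, sep = ".")
  out <- as.numeric(values)
  for (s in unique(strata[!is.na(values)])) {
    idx <- which(strata == s & !is.na(values))
    if (length(idx) < 2L) stop("stratum '", s, "' has fewer than 2 observations")
    sdv <- sd(values[idx])
    if (!is.finite(sdv) || sdv == 0) stop("stratum '", s, "' is constant")
    out[idx] <- (values[idx] - mean(values[idx])) / sdv
  }
  out
}

#' Liability thresholds from sex-specific prevalences
#'
#' Under the liability-threshold model a diagnosis marks liability above a
#' standard-normal threshold, so `tau_sex = qnorm(1 - prevalence_sex)`.
#' A sex stratum with no cases gets `+Inf` and is flagged in the
#' `boundary` attribute.
#'
#' @param diagnoses 0/1 vector, may contain `NA`
#' @param sex labels (`"M"`/`"F"`)
#' @return named vector `c(M =, F =)` with attributes `prevalence`, `boundary`
#' @export
estimate_thresholds <- function(diagnoses, sex) {
  ok <- !is.na(diagnoses)
  if (!any(ok)) stop("all diagnoses missing")
  if (!any(diagnoses[ok] == 1) || !any(diagnoses[ok] == 0))
    stop("need at least one case and one non-case")
  sexes <- c("M", "F")
  prev <- vapply(sexes, function(s) {
    i <- ok & sex == s
    if (!any(i)) NA_real_ else mean(diagnoses[i])
  }, numeric(1))
  tau <- qnorm(1 - prev)
  boundary <- !is.na(prev) & prev == 0
  structure(tau, prevalence = prev, boundary = boundary)
}

.cell_probs <- function(tau1, tau2, rho) {
  p00 <- pbvn(tau1, tau2, rho)
  p01 <- pnorm(tau1) - p00
  p10 <- pnorm(tau2) - p00
  p11 <- 1 - p00 - p01 - p10
  pmax(c(p00, p01, p10, p11), 1e-320)
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Maximum-likelihood latent correlation of two dichotomised standard-normal
#' variables: thresholds are set from the margins and `rho` maximises the
#' multinomial likelihood of the four cells under bivariate-normal quadrant
#' probabilities. With both thresholds at zero the model reduces to the
#' closed form `P(1,1) = 1/4 + asin(rho)/(2*pi)`.
#'
#' @param table 2x2 matrix of counts; rows index the first variable (0, 1),
#'   columns the second
#' @return list with `rho`, `se` (observed-information, `NA` at a boundary),
#'   `tau` (the two thresholds), and logical `boundary`
#' @export
tetrachoric_corr <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  n <- sum(table)
  if (n == 0) stop("empty table")
  p1 <- sum(table[2, ]) / n   # P(first = 1)
  p2 <- sum(table[, 2]) / n
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    warning("zero margin: tetrachoric correlation undefined; returning boundary")
    return(list(rho = NA_real_, se = NA_real_,
                tau = qnorm(1 - c(p1, p2)), boundary = TRUE))
  }
  tau1 <- qnorm(1 - p1); tau2 <- qnorm(1 - p2)
  counts <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  nll <- function(rho) -sum(counts * log(.cell_probs(tau1, tau2, rho)))
  opt <- optimize(nll, c(-0.9999, 0.9999), tol = 1e-9)
  rho <- opt$minimum
  boundary <- abs(rho) > 0.998
  if (boundary) {
    warning("tetrachoric estimate at boundary")
    rho <- sign(rho) * 1
    return(list(rho = rho, se = NA_real_, tau = c(tau1, tau2), boundary = TRUE))
  }
  h <- 1e-4
  info <- (nll(rho + h) - 2 * nll(rho) + nll(rho - h)) / h^2
  list(rho = rho, se = if (info > 0) 1 / sqrt(info) else NA_real_,
       tau = c(tau1, tau2), boundary = FALSE)
}

#' Polyserial correlation of a continuous measure and a binary diagnosis
#'
#' Two-step maximum likelihood under the joint model (normal `x`,
#' dichotomised normal liability for `y`): `x` is standardised by its sample
#' moments, the threshold comes from the prevalence of `y`, and `rho`
#' maximises the conditional Bernoulli likelihood
#' `P(y = 1 | x) = pnorm((rho*z - tau)/sqrt(1 - rho^2))`.
#'
#' @param x continuous values
#' @param y 0/1 diagnoses
#' @return list with `rho`, `se`, `tau`, `boundary`
#' @export
polyserial_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10L) stop("need at least 10 complete pairs")
  if (length(unique(y)) < 2L) stop("y is constant")
  z <- (x - mean(x)) / sd(x)
  tau <- qnorm(1 - mean(y))
  nll <- function(rho) {
    q <- (rho * z - tau) / sqrt(1 - rho^2)
    -sum(ifelse(y == 1, pnorm(q, log.p = TRUE), pnorm(-q, log.p = TRUE)))
  }
  opt <- optimize(nll, c(-0.9999, 0.9999), tol = 1e-9)
  rho <- opt$minimum
  boundary <- abs(rho) > 0.998
  if (boundary) return(list(rho = sign(rho), se = NA_real_, tau = tau, boundary = TRUE))
  h <- 1e-4
  info <- (nll(rho + h) - 2 * nll(rho) + nll(rho - h)) / h^2
  list(rho = rho, se = if (info > 0) 1 / sqrt(info) else NA_real_,
       tau = tau, boundary = FALSE)
}
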