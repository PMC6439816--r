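#' Simulate twin-pair phenotypes under a bivariate liability model
#'
#' Draws, for each zygosity-by-sex group in `spec$n_pairs`, latent
#' `(trait1, liability1, trait2, liability2)` vectors from the correlation
#' matrix implied by the spec ([implied_moments()], standardised), converts
#' each liability to a binary diagnosis by comparing it against the
#' sex-specific threshold, and applies MCAR missingness at the configured
#' rates. The result is a long-format [phenotype_table()]. DZ opposite-sex
#' pairs place the male twin first.
#'
#' Determinism: the RNG state is seeded from `spec$seed` through a dedicated
#' substream, so the same spec always yields the same table regardless of
#' what else has used the global RNG.
#'
#' @param spec a [twin_spec()]
#' @param trait,diagnosis output column names
#' @param age_cohort assessment wave recorded on every row (9, 12, 15, 18)
#' @return a [phenotype_table()] with one trait and one diagnosis column
#' @export
simulate_twin_pairs <- function(spec, trait = "trait", diagnosis = "diagnosis",
                                age_cohort = 9L) {
  stopifnot(inherits(spec, "twin_spec"))
  groups <- list(
    MZM = list(zyg = "MZ", sex = c("M", "M")),
    DZM = list(zyg = "DZ", sex = c("M", "M")),
    MZF = list(zyg = "MZ", sex = c("F", "F")),
    DZF = list(zyg = "DZ", sex = c("F", "F")),
    DZOS = list(zyg = "DZ", sex = c("M", "F")))
  R <- list(MZ = cov2cor(implied_moments(spec, "MZ")),
            DZ = cov2cor(implied_moments(spec, "DZ")))
  L <- lapply(R, chol)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(spec$seed, "twin_pairs"))

  out <- vector("list", length(groups))
  pair_offset <- 0L
  for (g in names(groups)) {
    n <- spec$n_pairs[[g]]
    if (n == 0) { out[[g]] <- NULL; next }
    z <- matrix(rnorm(4 * n), n, 4) %*% L[[groups[[g]]$zyg]]
    sexes <- groups[[g]]$sex
    tau1 <- spec$tau[[sexes[1]]]
    tau2 <- spec$tau[[sexes[2]]]
    dx1 <- as.integer(z[, 2] > tau1)
    dx2 <- as.integer(z[, 4] > tau2)
    t1 <- z[, 1]; t2 <- z[, 3]
    mr <- spec$missing_rate
    if (mr[["trait"]] > 0) {
      t1[runif(n) < mr[["trait"]]] <- NA_real_
      t2[runif(n) < mr[["trait"]]] <- NA_real_
    }
    if (mr[["diagnosis"]] > 0) {
      dx1[runif(n) < mr[["diagnosis"]]] <- NA_integer_
      dx2[runif(n) < mr[["diagnosis"]]] <- NA_integer_
    }
    ids <- sprintf("%s%06d", g, pair_offset + seq_len(n))
    pair_offset <- pair_offset + n
    out[[g]] <- data.frame(
      pair_id = rep(ids, each = 2L),
      twin_order = rep(1:2, n),
      zygosity = g,
      sex = rep(sexes, n),
      age_cohort = as.integer(age_cohort),
      trait = as.vector(rbind(t1, t2)),
      diagnosis = as.vector(rbind(dx1, dx2)),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(pair_id = character(), twin_order = integer(),
                     zygosity = character(), sex = character(),
                     age_cohort = integer(), trait = numeric(),
                     diagnosis = integer())
  }
  names(df)[names(df) == "trait"] <- trait
  names(df)[names(df) == "diagnosis"] <- diagnosis
  rownames(df) <- NULL
  phenotype_table(df, traits = trait, diagnoses = diagnosis)
}
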