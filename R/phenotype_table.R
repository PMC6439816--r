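#' Construct and validate a twin phenotype table
#'
#' The internal phenotype container is a long-format data frame with two rows
#' per twin pair and columns `pair_id`, `twin_order` (1 or 2), `zygosity`
#' (`MZM`, `DZM`, `MZF`, `DZF`, `DZOS`), `sex` (`M`/`F`), `age_cohort`
#' (9, 12, 15 or 18), followed by the named continuous measures and the named
#' binary diagnoses. The measure/diagnosis column names are carried in
#' attributes `traits` and `diagnoses`.
#'
#' Validation enforces the pair structure: every `pair_id` occurs exactly
#' twice with twin orders 1 and 2, zygosity is identical within a pair, and
#' pair sexes match the zygosity label (discordant for `DZOS`, concordant
#' male for `MZM`/`DZM`, concordant female for `MZF`/`DZF`).
#'
#' @param df data frame in the layout above
#' @param traits character vector of continuous measure column names
#' @param diagnoses character vector of binary diagnosis column names
#' @return the validated data frame with class `phenotype_table`
#' @export
phenotype_table <- function(df, traits = character(), diagnoses = character()) {
  req <- c("pair_id", "twin_order", "zygosity", "sex", "age_cohort")
  miss <- setdiff(c(req, traits, diagnoses), names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$pair_id <- as.character(df$pair_id)
  df$twin_order <- as.integer(df$twin_order)
  df$zygosity <- as.character(df$zygosity)
  df$sex <- as.character(df$sex)
  df$age_cohort <- as.integer(df$age_cohort)

  bad <- setdiff(unique(df$zygosity), c("MZM", "DZM", "MZF", "DZF", "DZOS"))
  if (length(bad)) stop("unknown zygosity group(s): ", paste(bad, collapse = ", "))
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (!all(df$age_cohort %in% c(9L, 12L, 15L, 18L)))
    stop("age_cohort must be one of 9, 12, 15, 18")

  key <- paste(df$pair_id, df$twin_order)
  if (anyDuplicated(key))
    stop("format error: duplicate (pair_id, twin_order): ",
         key[which(duplicated(key))[1]])
  tab <- table(df$pair_id)
  if (any(tab != 2L))
    stop("format error: each pair_id must appear exactly twice; offending pair: ",
         names(tab)[which(tab != 2L)[1]])

  ord <- order(df$pair_id, df$twin_order)
  odd <- seq_len(nrow(df)) %% 2L == 1L
  d1 <- df[ord, ][odd, ]
  d2 <- df[ord, ][!odd, ]
  if (any(d1$twin_order != 1L) || any(d2$twin_order != 2L))
    stop("format error: twin_order within a pair must be {1, 2}")
  zyg_bad <- d1$pair_id[d1$zygosity != d2$zygosity]
  if (length(zyg_bad))
    stop("validation error: zygosity differs within pair ", zyg_bad[1])
  same_sex <- d1$sex == d2$sex
  lab_sex <- c(MZM = "M", DZM = "M", MZF = "F", DZF = "F", DZOS = "")[d1$zygosity]
  ok <- ifelse(d1$zygosity == "DZOS", !same_sex, same_sex & d1$sex == lab_sex)
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop("validation error: sexes (", d1$sex[i], ",", d2$sex[i],
         ") inconsistent with zygosity ", d1$zygosity[i],
         " in pair ", d1$pair_id[i])
  }
  for (dcol in diagnoses) {
    v <- df[[dcol]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop("diagnosis column '", dcol, "' must be 0/1 or missing")
    df[[dcol]] <- as.integer(v)
  }
  for (tcol in traits) df[[tcol]] <- as.numeric(df[[tcol]])

  structure(df, traits = traits, diagnoses = diagnoses,
            class = c("phenotype_table", "data.frame"))
}

#' Column roles of a phenotype table
#' @param x a [phenotype_table()]
#' @return character vector of trait (or diagnosis) column names
#' @export
pheno_traits <- function(x) attr(x, "traits")

#' @rdname pheno_traits
#' @export
pheno_diagnoses <- function(x) attr(x, "diagnoses")

# wide (one row per pair) view of selected columns; suffixes .1/.2
pair_wide <- function(pt, cols) {
  ord <- order(pt$pair_id, pt$twin_order)
  d <- as.data.frame(pt)[ord, , drop = FALSE]
  odd <- seq_len(nrow(d)) %% 2L == 1L
  d1 <- d[odd, c("pair_id", "zygosity", "sex", cols), drop = FALSE]
  d2 <- d[!odd, c("sex", cols), drop = FALSE]
  names(d2) <- paste0(names(d2), ".2")
  names(d1)[names(d1) %in% c("sex", cols)] <-
    paste0(c("sex", cols), ".1")
  cbind(d1, d2)
}
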