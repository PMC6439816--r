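#' Read a twin phenotype table from TSV
#'
#' Reads a tab-delimited file with a header row in the long layout of
#' [phenotype_table()] (two rows per pair) and validates it. Empty strings
#' and `"NA"` are treated as missing. Which columns are continuous measures
#' and which are diagnoses is declared by the caller (or taken from an
#' [analysis_config()]).
#'
#' @param path file path
#' @param traits,diagnoses column-role declarations
#' @return a validated [phenotype_table()]
#' @export
read_phenotypes <- function(path, traits = character(), diagnoses = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, na.strings = c("", "NA"),
                   stringsAsFactors = FALSE, check.names = FALSE)
  phenotype_table(df, traits = traits, diagnoses = diagnoses)
}

#' Write a phenotype table to TSV
#'
#' Inverse of [read_phenotypes()]: tab-delimited, header, missing values as
#' empty strings, reals at full precision (17 significant digits) so a
#' write-then-read round trip reproduces the table exactly.
#'
#' @param pt a [phenotype_table()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_phenotypes <- function(pt, path) {
  d <- as.data.frame(pt)
  for (nm in pheno_traits(pt)) d[[nm]] <- .fmt_real(d[[nm]], digits = 17)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

.fmt_real <- function(x, digits = 6) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- NA
  out
}
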