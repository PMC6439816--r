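#' GWAS summary statistics container
#'
#' Per-variant discovery association records used as PRS weights: effect
#' allele, other allele, effect size on the log-odds (binary discovery
#' phenotype) or linear scale, its SE, p-value and discovery sample size.
#'
#' @param df data frame with columns
#'   `id, chrom, pos, effect_allele, other_allele, beta, se, p, n`
#' @return object of class `gwas_sumstats` (a validated data frame)
#' @export
gwas_sumstats <- function(df) {
  req <- c("id", "chrom", "pos", "effect_allele", "other_allele", "beta", "se", "p", "n")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("format error: missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate variant ids")
  if (any(df$effect_allele == df$other_allele))
    stop("effect_allele must differ from other_allele")
  if (any(!is.finite(df$p) | df$p <= 0 | df$p > 1)) stop("p must lie in (0, 1]")
  if (any(df$se < 0, na.rm = TRUE)) stop("se must be >= 0")
  structure(as.data.frame(df)[req], class = c("gwas_sumstats", "data.frame"))
}

#' Read GWAS summary statistics from TSV
#'
#' Reads a tab-delimited file and maps its columns onto the internal schema
#' through `col_map` (defaults follow the common
#' SNP/CHR/BP/A1/A2/BETA/SE/P/N convention). Rows with `p` outside `(0, 1]`,
#' missing effect size, or a duplicated id (first occurrence kept) are
#' dropped; the number dropped for each reason is reported via `message()`
#' and attached as attribute `dropped`.
#'
#' @param path file path
#' @param col_map named list mapping internal names
#'   (`id, chrom, pos, effect_allele, other_allele, beta, se, p, n`) to file
#'   column names
#' @param or_column optional name of an odds-ratio column to be used instead
#'   of `beta`; it is converted with `beta = log(OR)`
#' @return a [gwas_sumstats()] with attribute `dropped`
#' @export
read_summary_stats <- function(path,
                               col_map = list(id = "SNP", chrom = "CHR", pos = "BP",
                                              effect_allele = "A1", other_allele = "A2",
                                              beta = "BETA", se = "SE", p = "P", n = "N"),
                               or_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"), check.names = FALSE)
  defaults <- list(id = "SNP", chrom = "CHR", pos = "BP",
                   effect_allele = "A1", other_allele = "A2",
                   beta = "BETA", se = "SE", p = "P", n = "N")
  col_map <- modifyList(defaults, col_map)
  if (!is.null(or_column)) col_map$beta <- or_column
  need <- unlist(col_map)
  absent <- setdiff(need, names(raw))
  if (length(absent)) stop("format error: missing required column(s): ",
                           paste(absent, collapse = ", "))
  df <- data.frame(id = as.character(raw[[col_map$id]]),
                   chrom = raw[[col_map$chrom]],
                   pos = as.integer(raw[[col_map$pos]]),
                   effect_allele = toupper(raw[[col_map$effect_allele]]),
                   other_allele = toupper(raw[[col_map$other_allele]]),
                   beta = as.numeric(raw[[col_map$beta]]),
                   se = as.numeric(raw[[col_map$se]]),
                   p = as.numeric(raw[[col_map$p]]),
                   n = as.integer(raw[[col_map$n]]),
                   stringsAsFactors = FALSE)
  if (!is.null(or_column)) df$beta <- log(df$beta)
  dropped <- c(bad_p = 0L, missing_beta = 0L, duplicate_id = 0L)
  bad_p <- !is.finite(df$p) | df$p <= 0 | df$p > 1
  dropped["bad_p"] <- sum(bad_p); df <- df[!bad_p, ]
  mb <- !is.finite(df$beta)
  dropped["missing_beta"] <- sum(mb); df <- df[!mb, ]
  dup <- duplicated(df$id)
  dropped["duplicate_id"] <- sum(dup); df <- df[!dup, ]
  if (sum(dropped) > 0)
    message("read_summary_stats: dropped ", sum(dropped), " row(s) [",
            paste(names(dropped), dropped, sep = "=", collapse = ", "), "]")
  out <- gwas_sumstats(df)
  attr(out, "dropped") <- dropped
  out
}

#' Write summary statistics to TSV
#' @param ss a [gwas_sumstats()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_summary_stats <- function(ss, path) {
  d <- as.data.frame(ss)
  names(d) <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N")
  for (nm in c("BETA", "SE", "P")) d[[nm]] <- .fmt_real(d[[nm]], digits = 17)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write result tables as deterministic TSVs
#'
#' One TSV per logical table, with a fixed column order (the order the table
#' carries) and reals serialised at a fixed precision, so the same input
#' always produces byte-identical files. Empty tables yield header-only
#' files.
#'
#' @param tables named list of data frames
#' @param out_dir output directory (created if needed)
#' @param digits significant digits for reals
#' @return character vector of file paths, invisibly
#' @export
write_results <- function(tables, out_dir, digits = 6) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    d <- as.data.frame(tables[[nm]])
    for (col in names(d)) if (is.numeric(d[[col]]) && !is.integer(d[[col]]))
      d[[col]] <- .fmt_real(d[[col]], digits = digits)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    paths <- c(paths, p)
  }
  invisible(paths)
}
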