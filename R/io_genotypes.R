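#' Genotype container
#'
#' Holds hard-call genotypes as an individuals x variants dosage matrix
#' counting copies of `allele1` (0, 1, 2 or `NA`), with the variant map
#' (`id`, `chrom`, `pos`, `allele1`, `allele2`) and individual ids.
#'
#' @param ids character vector of individual ids (unique)
#' @param variants data frame with columns `id, chrom, pos, allele1, allele2`
#' @param dosage numeric matrix, `length(ids)` rows, `nrow(variants)` columns
#' @return object of class `genotype_data`
#' @export
genotype_data <- function(ids, variants, dosage) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  req <- c("id", "chrom", "pos", "allele1", "allele2")
  if (!all(req %in% names(variants))) stop("variant table needs columns ", paste(req, collapse = ", "))
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (nrow(dosage) != length(ids) || ncol(dosage) != nrow(variants))
    stop("dosage dimensions inconsistent with ids/variants")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (!all(dosage %in% c(0, 1, 2) | is.na(dosage)))
    stop("dosages must be 0/1/2 or missing (hard calls only)")
  dimnames(dosage) <- list(ids, variants$id)
  structure(list(ids = ids, variants = as.data.frame(variants), dosage = dosage),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d individuals x %d variants, %.2f%% missing\n",
              length(x$ids), nrow(x$variants), 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Read genotypes from PLINK-1 binary or VCF
#'
#' For `format = "plink1"`, `prefix_or_path` is the path prefix of a
#' `bed`/`bim`/`fam` triplet; the bed file must be SNP-major (magic bytes
#' `0x6c 0x1b 0x01`). Dosages count the bim A1 allele (`allele1`). For
#' `format = "vcf"`, `allele1` is the REF allele and dosages count REF
#' copies from the GT field; records must be diploid.
#'
#' @param prefix_or_path plink prefix or vcf path
#' @param format `"plink1"` or `"vcf"`
#' @return a [genotype_data()]
#' @export
read_genotypes <- function(prefix_or_path, format = c("plink1", "vcf")) {
  format <- match.arg(format)
  if (format == "plink1") .read_plink1(prefix_or_path) else .read_vcf(prefix_or_path)
}

.read_plink1 <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  if (!all(file.exists(paths)))
    stop("plink triplet incomplete; need ", paste(paths, collapse = ", "))
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "allele1", "allele2"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("bed magic-number mismatch in ", paths[1])
  if (raw[3] != as.raw(0x01)) stop("bed file is not SNP-major")
  body <- raw[-(1:3)]
  if (length(body) != ceiling(n / 4) * m) stop("bed payload size inconsistent with bim/fam")
  # unpack 2-bit codes: 00 hom A1 (dosage 2), 10 het (1), 11 hom A2 (0), 01 missing
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8)
  codes <- bits[c(TRUE, FALSE), , drop = FALSE] + 2L * bits[c(FALSE, TRUE), , drop = FALSE]
  codes <- matrix(as.vector(codes), nrow = ceiling(n / 4) * 4)[seq_len(n), , drop = FALSE]
  lut <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  dosage <- matrix(lut[codes + 1L], n, m)
  ids <- if (any(duplicated(fam$V2))) paste(fam$V1, fam$V2, sep = "_") else fam$V2
  genotype_data(ids, bim[c("id", "chrom", "pos", "allele1", "allele2")], dosage)
}

.read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_clean <- gsub("\\|", "/", gt)
  alleles <- strsplit(as.vector(gt_clean), "/", fixed = TRUE)
  nall <- lengths(alleles)
  if (any(!is.na(as.vector(gt_clean)) & nall != 2L))
    stop("non-diploid GT encountered (ploidy != 2)")
  ref_count <- function(g) {
    if (is.na(g) || g %in% c("./.", ".")) return(NA_real_)
    sum(strsplit(g, "/", fixed = TRUE)[[1]] == "0")
  }
  dosage <- t(apply(gt_clean, c(1, 2), ref_count))  # individuals x variants
  ids <- colnames(gt)
  vid <- fix[, "ID"]
  vid[is.na(vid) | vid == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(vid) | vid == "."]
  variants <- data.frame(id = vid, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         allele1 = fix[, "REF"], allele2 = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  genotype_data(ids, variants, dosage)
}

#' Write genotypes as a PLINK-1 bed/bim/fam triplet
#'
#' SNP-major bed with the standard magic bytes; dosages are encoded as
#' counts of the bim A1 allele, the exact inverse of [read_genotypes()].
#' Family/phenotype fam columns are filled with placeholders.
#'
#' @param geno a [genotype_data()]
#' @param prefix output path prefix
#' @param sex optional per-individual sex codes (`"M"`/`"F"`) for the fam file
#' @return `prefix`, invisibly
#' @export
write_plink1 <- function(geno, prefix, sex = NULL) {
  n <- length(geno$ids); m <- nrow(geno$variants)
  fam <- data.frame(fid = geno$ids, iid = geno$ids, pat = 0, mat = 0,
                    sex = if (is.null(sex)) 0 else ifelse(sex == "M", 1L, 2L),
                    phe = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(geno$variants$chrom, geno$variants$id, 0,
                    geno$variants$pos, geno$variants$allele1, geno$variants$allele2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  code <- matrix(1L, ceiling(n / 4) * 4, m)  # 01 = missing
  d <- geno$dosage
  code[seq_len(n), ][!is.na(d) & d == 2] <- 0L
  code[seq_len(n), ][!is.na(d) & d == 1] <- 2L
  code[seq_len(n), ][!is.na(d) & d == 0] <- 3L
  bits <- rbind(code %% 2L, code %/% 2L)  # interleave low/high bit per sample
  idx <- as.vector(matrix(seq_len(nrow(bits)), nrow = 2, byrow = TRUE))
  bits <- bits[idx, , drop = FALSE]
  payload <- packBits(as.logical(bits), type = "raw")
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(payload, con)
  invisible(prefix)
}
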