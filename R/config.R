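#' Analysis configuration
#'
#' Bundles the run-level choices: which trait/diagnosis pairings to model and
#' with which family, the PRS p-value selection thresholds (with the primary
#' one), LD-clumping parameters, the number of stratification PCs, the FDR
#' level, and the master seed.
#'
#' @param pairings list of lists with elements `trait`, `diagnosis`, and
#'   `family` (one of `"ACE"`, `"ADE-s"`, `"saturated-only"`)
#' @param thresholds ascending p-value grid for PRS variant selection
#' @param primary_threshold member of `thresholds` used for the headline tests
#' @param clump_r2,clump_kb LD-clumping r-squared cut and window (kb)
#' @param n_pcs number of principal components used as covariates
#' @param fdr_level nominal false discovery rate
#' @param seed non-negative integer master seed
#' @return object of class `analysis_config`
#' @export
analysis_config <- function(pairings = list(),
                            thresholds = c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.5, 1.0),
                            primary_threshold = 0.5,
                            clump_r2 = 0.1, clump_kb = 250,
                            n_pcs = 10L, fdr_level = 0.05, seed = 1L) {
  thresholds <- as.numeric(thresholds)
  if (is.unsorted(thresholds, strictly = TRUE)) stop("thresholds must be sorted ascending")
  if (!primary_threshold %in% thresholds) stop("primary_threshold must be one of thresholds")
  if (length(seed) != 1L || is.na(seed) || seed < 0) stop("seed must be a non-negative integer")
  for (p in pairings) {
    if (!all(c("trait", "diagnosis", "family") %in% names(p)))
      stop("each pairing needs trait, diagnosis, family")
    if (!p$family %in% c("ACE", "ADE-s", "saturated-only"))
      stop("unknown model family: ", p$family)
  }
  structure(list(pairings = pairings, thresholds = thresholds,
                 primary_threshold = primary_threshold,
                 clump_r2 = clump_r2, clump_kb = clump_kb,
                 n_pcs = as.integer(n_pcs), fdr_level = fdr_level,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#' @param path YAML file
#' @return [analysis_config()] for the reader; `path` invisibly for the writer
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y)
}

#' @rdname read_config
#' @param config an [analysis_config()]
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
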