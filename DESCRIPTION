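Package: twinprs
Title: Joint Categorical/Continuous Twin Models and Polygenic Score
    Association Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits bivariate liability-threshold twin models by maximum
    likelihood to estimate genetic and environmental correlations between a
    continuous trait and a rare binary diagnosis, with saturated twin
    correlations (Pearson, tetrachoric, polyserial), ACE/ADE model families
    including sibling interaction, BIC/likelihood-ratio model selection, and
    probandwise concordances.  Also provides a polygenic risk score pipeline
    (allele harmonisation, LD clumping, multi-threshold scoring, principal
    component stratification covariates, cluster-robust association tests with
    false discovery rate control) and a synthetic twin-cohort generator
    (phenotypes under the generating twin model; genotypes with LD blocks and
    optional population structure; simulated discovery summary statistics)
    so that every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    pracma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
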