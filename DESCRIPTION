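Package: trivarmix
Title: Trivariate Causal Mixture Models for Polygenic Overlap from GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the pattern of polygenic overlap among three complex
    phenotypes from genome-wide association study (GWAS) summary statistics
    using a causal mixture model with eight components. Observed z-scores are
    modeled through a linkage-disequilibrium (LD) weighted sum of direct
    effects; per-variant densities are obtained by numerical inversion of the
    characteristic function and combined into a composite likelihood that is
    maximized stepwise (univariate, bivariate, trivariate). Includes
    feasibility bounds and a maximum-entropy naive expectation for the triple
    overlap, LD reference construction from genotypes or PLINK r2 tables,
    summary-statistics harmonization and quality control with seeded random
    pruning, a synthetic-data generator covering block-LD genotypes and
    scenario-based causal-set designs, multi-seed fitting with
    representative-run selection, and JSON/Euler-area result export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
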