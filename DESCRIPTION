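Package: camelroutes
Title: Population Genomics of Global Dromedary Structure and Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete inference chain for reduced-representation (ddRAD) SNP
    studies of population structure and effective migration in dromedaries:
    screening for interspecific (Bactrian camel) hybrids from dual-reference
    read-assignment counts, PLINK-style quality-control filtering with
    identity-by-state relatedness pruning, diversity and differentiation
    statistics (heterozygosities, inbreeding coefficients, rarefied allelic
    richness, Weir-Cockerham FST with permutation tests, hierarchical AMOVA),
    principal-component and model-based ancestry analysis with cross-validated
    choice of the number of clusters, Bayesian FST-outlier scanning with
    gene-window annotation, effective-migration-surface estimation on a deme
    grid over a habitat polygon, and preparation of calibrated multi-locus
    inputs for Extended Bayesian Skyline demographic analysis. A synthetic-data
    module generates every input with known ground truth so the whole chain is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
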