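Package: paradiverge
Title: Structural and Functional Divergence of Duplicated Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses of divergence between paralogous gene clusters created by
    whole genome duplication. Implements two complementary pipelines: (1)
    structural divergence of protein clusters via normalized Kyte-Doolittle
    hydropathy profiles, multi-metric average-linkage hierarchical clustering
    with cophenetic and inconsistency-coefficient diagnostics, and stepwise
    linear discriminant analysis with Mahalanobis variable selection; (2)
    type-I functional divergence between paralog clusters via the coefficient
    theta = 1 - r (the complement of the between-cluster evolutionary rate
    correlation), estimated by maximum likelihood under a gamma-Poisson
    two-state mixture over per-site Fitch parsimony substitution counts, with
    a likelihood-ratio test and site-specific posterior profiles. Includes
    synthetic-data generators emulating the statistical structure the analyses
    assume, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
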