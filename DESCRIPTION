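Package: xqtl
Title: Integrative Proteogenomic QTL Mapping, Colocalization, Mediation
    and Candidate-Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for integrative genetic analysis of
    molecular phenotypes in bulk tissue. Implements isobaric (TMT)
    reporter-ion protein quantification from peptide-spectrum-match
    tables, hidden-factor correction with inverse-normal transformation,
    cis and trans QTL mapping with permutation-calibrated
    beta-approximated empirical p-values and Storey q-values,
    five-hypothesis Bayesian colocalization of association signals,
    transcript-mediation classification of protein QTLs against a
    permutation null, summary-based Mendelian randomization with the
    HEIDI heterogeneity test, and order-statistics aggregation of ranked
    evidence sources with a protein-interaction connectivity score. A
    synthetic-data generator emulates the statistical structure of a
    multi-batch proteogenomic study so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
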