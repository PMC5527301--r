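Package: skinmatch
Title: Couple Matching and Community Analysis for Skin Microbiome OTU Tables
Version: 0.1.0
Authors@R: person("skinmatch", "developers", role = c("aut", "cre"),
    email = "skinmatch@example.org")
Description: Analysis pipeline for household-structured skin microbiome
    surveys. Reads QIIME-classic OTU tables and mapping files, performs
    depth filtering and rarefaction, alpha diversity (Shannon, observed
    OTUs) with multiple-rarefaction sweeps and nonparametric two-sample
    tests, Bray-Curtis distances and principal-coordinates analysis,
    nearest-neighbor self/partner/other matching with analytic chance
    baselines, one-factor PERMANOVA with permutation tests, a
    derangement-based couple-pairing permutation null for both the
    PERMANOVA pseudo-F and the cross-validated error of a random-forest
    classifier, Dufrene-Legendre indicator species analysis, core-OTU
    detection and sex-enrichment tables. Ships a hierarchical
    Dirichlet-multinomial community simulator that emulates a
    couples-cohort study design so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
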