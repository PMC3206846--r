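Package: symprofiler
Title: Clone-Library and T-RFLP Profiling of Host-Associated Bacterial
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end workflow for characterizing and comparing
    host-associated bacterial communities from 16S rRNA gene data.
    Covers OTU clustering of clone-library sequences at a fixed identity
    threshold, alpha diversity (observed richness, Chao1, Shannon,
    evenness) and analytic rarefaction, in-silico restriction digestion
    to predict terminal restriction fragments (T-RFs), processing of
    empirical T-RFLP electropherograms (variable-percentage-threshold
    standardization and cross-sample T-RF alignment), matching of
    empirical T-RFs to sequence-based predictions under size-dependent
    tolerance bins, community comparison (Bray-Curtis, non-metric MDS,
    ANOSIM, likelihood-ratio G tests), phylogenetic community metrics
    (Tajima-Nei distances, AMOVA, LIBSHUFF, P-test, NRI/NTI), rule-based
    classification of symbionts as specialists or generalists, and a
    synthetic-data generator that emulates replicated sponge, tunicate
    and seawater clone libraries with matched electropherograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    Biostrings,
    phangorn,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
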