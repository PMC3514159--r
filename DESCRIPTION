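Package: seedenrich
Title: Interactor Catalogs with Direct and Indirect Gene-Set Enrichment
    for Protein Interaction Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for curating binary protein-interaction screen results
    and testing them for functional enrichment.  Merges bait-prey hit
    lists from two-configuration yeast two-hybrid screens into an
    annotated interactor catalog with bimolecular fluorescence
    complementation (BiFC) localization calls; tests the direct
    interactor set for gene-set over-representation with the one-sided
    Fisher exact test inside the tested ORFeome universe, including the
    non-monotonized p*m/rank correction dialect found in published
    screen reports; and tests second-degree (indirect) interactors with
    a seed-randomization permutation null, empirical false discovery
    rates, and per-source Bonferroni correction.  A synthetic-data
    module generates networks, gene-set collections and seed sets with
    planted enrichment so every stage can be benchmarked offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
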