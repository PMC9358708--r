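Package: ecoassembly
Title: Abundant and Rare Subcommunity Assembly with Phylogenetic and
    Raup-Crick Null Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bacterial community assembly in
    environmental samples. Partitions taxa into abundant, intermediate and
    rare categories by relative abundance; computes taxonomic (Bray-Curtis)
    and phylogenetic (beta mean nearest taxon distance) turnover; infers
    deterministic versus stochastic assembly processes with beta nearest
    taxon index (betaNTI) tip-shuffle null models and the Bray-Curtis based
    Raup-Crick metric (RC-Bray); and relates diversity and assembly balance
    to environmental divergences with Mantel permutation tests, Spearman
    correlations and rank-sum comparisons. Includes a neighbor-joining tree
    builder, rarefaction utilities, and a synthetic metacommunity generator
    with tunable selection, dispersal limitation and drift for validating
    the inference by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
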