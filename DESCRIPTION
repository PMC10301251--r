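Package: ilsnet
Title: Gene-Tree Discordance, Coalescent ILS Tests, and Hybridization
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gene-tree/species-tree conflict and
    testing its causes in phylogenomic datasets. Provides bipartition-based
    concordance mapping with internode certainty (ICA), quartet-sampling
    branch scores (QC/QD/QI), quartet-score species-tree estimation with
    coalescent-unit branch lengths, a multispecies-coalescent simulation
    test of whether incomplete lineage sorting alone explains observed
    Robinson-Foulds discordance, and single-reticulation network fitting by
    rooted-triple pseudo-likelihood with inheritance probabilities. Includes
    a seeded synthetic-data generator (species trees, coalescent and
    network gene trees, estimation noise) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
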