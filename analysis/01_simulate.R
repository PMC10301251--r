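#!/usr/bin/env Rscript
# Build the two study-style synthetic datasets everything downstream uses:
#   results/fixtures/msc      - 9 taxa, 800 genes, ILS only
#   results/fixtures/network  - same guide tree plus one reticulation into
#                               the tip "A" from the (F,G) clade, gamma 0.5
# Both carry gene-tree estimation noise (5% NNI edges, 2% missing taxa).

suppressPackageStartupMessages(library(ilsnet))

species_tree <- parse_newick(
  "(((((A:1,B:1):1,C:2):1,(D:1,E:1):2):1,((F:1,G:1):2,H:3):1):1,O:6);")
cfg <- sim_config(seed = 20231, n_genes = 800, nni_noise_prob = 0.05,
                  missing_prob = 0.02)

dir.create("results/fixtures", recursive = TRUE, showWarnings = FALSE)
generate_dataset(species_tree, cfg, "results/fixtures/msc")
generate_dataset(network_model(species_tree, recipient = "A",
                               donor = c("F", "G"), gamma = 0.5, tau = 0.5),
                 cfg, "results/fixtures/network")

for (d in c("msc", "network")) {
  n <- length(readLines(file.path("results/fixtures", d, "gene_trees.nwk")))
  cat(sprintf("fixture %-8s: %d gene trees, 9 taxa (outgroup O)\n", d, n))
}
cat("guide tree:", write_newick(species_tree), "\n")
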