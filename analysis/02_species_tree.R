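#!/usr/bin/env Rscript
# Species-tree step. Two things happen here:
#  1. A quartet-score search on the network-fixture gene trees, to show how
#     a gamma = 0.5 hybrid distorts summary species-tree inference (the
#     hybrid tip gets pulled toward its donor lineage).
#  2. The coalescent-unit (CU) guide trees used downstream: internal branch
#     lengths estimated from quartet concordance fractions on the known
#     generating topology, separately for each fixture.

suppressPackageStartupMessages(library(ilsnet))

truth <- parse_newick(readLines("results/fixtures/network/true_species_tree.nwk"))

genes_net <- read_gene_trees("results/fixtures/network/gene_trees.nwk")
est <- infer_species_tree(genes_net, seed = 1)
cat("generating topology :", write_newick(ape::unroot(truth)), "\n")
cat("quartet-score search:", write_newick(est), "\n")
cat("RF distance         :", rf_distance(est, ape::unroot(truth)),
    "(> 0 expected: the hybrid tip A is pulled toward its donor clade)\n\n")
writeLines(write_newick(est), "results/species_tree_inferred.nwk")

for (fx in c("msc", "network")) {
  genes <- read_gene_trees(file.path("results/fixtures", fx, "gene_trees.nwk"))
  model <- estimate_coalescent_branch_lengths(truth, genes, draws = 2000,
                                              seed = 2, outgroup = "O")
  tab <- attr(model, "branch_estimates")
  writeLines(write_newick(model),
             sprintf("results/species_tree_cu_%s.nwk", fx))
  write.table(tab, sprintf("results/branch_lengths_%s.tsv", fx),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("CU estimates on the", fx, "fixture (p = concordant quartet fraction):\n")
  print(tab, row.names = FALSE)
  cat("\n")
}
cat("Reticulate gene flow depresses p around the donor and recipient\n")
cat("branches, so the network fixture's CU estimates undershoot there.\n")
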