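# Shared fixtures and independent oracles, built in code.

# Random binary tree over n taxa (ape's rtree, unrooted unless stated).
random_unrooted_tree <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  ape::unroot(ape::rtree(n, tip.label = sample(labels)))
}

# Brute-force split enumeration independent of the package internals:
# every internal edge's tip set as a sorted "a b c" string, orientation
# fixed by the side not containing the alphabetically first taxon.
brute_splits <- function(phy) {
  phy <- ape::unroot(phy)
  taxa <- sort(phy$tip.label)
  ntip <- ape::Ntip(phy)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (p in pp) {
    tips <- sort(labs[p])
    if (length(tips) <= 1L || length(tips) >= length(taxa) - 1L) next
    if (taxa[1] %in% tips) tips <- setdiff(taxa, tips)
    out <- c(out, paste(sort(tips), collapse = " "))
  }
  unique(out)
}

# Brute-force symmetric-difference RF distance.
brute_rf <- function(t1, t2) {
  s1 <- brute_splits(t1)
  s2 <- brute_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# The 9-taxon study-style fixture: outgroup O, a tip recipient and a
# distant donor clade (regraft crosses >= 3 edges).
fixture_species_tree <- function() {
  parse_newick(
    "(((((A:1,B:1):1,C:2):1,(D:1,E:1):2):1,((F:1,G:1):2,H:3):1):1,O:6);")
}

fixture_network <- function(gamma = 0.5, tau = 0.5) {
  network_model(fixture_species_tree(), recipient = "A",
                donor = c("F", "G"), gamma = gamma, tau = tau)
}
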