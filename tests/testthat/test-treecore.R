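test_that("parse_newick reads topology, lengths and supports", {
  t4 <- parse_newick("(A,B,(C,D));")
  expect_equal(sort(t4$tip.label), c("A", "B", "C", "D"))
  bs <- bipartition_set(t4)
  expect_equal(bs$split, "A,B|C,D")

  t3 <- parse_newick("((A:1,B:1)95:0.5,C:2);")
  expect_true(ape::is.rooted(t3))
  expect_true(95 %in% t3$support)
  expect_equal(sort(t3$edge.length), c(0.5, 1, 1, 2))

  tc <- parse_newick("((A:1,B:1)[95]:0.5,C:2);", support_convention = "comment")
  expect_true(95 %in% tc$support)
})

test_that("malformed newick fails with the character offset", {
  expect_error(parse_newick("((A,B)"), "unclosed")
  expect_error(parse_newick("(A,B))C;"), "offset")
  expect_error(parse_newick("(A,B,(C,D))"), "missing ';'")
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")
  expect_error(parse_newick("((A:-1,B:1),C:1);"), "negative")
})

test_that("newick round trip preserves topology, lengths and supports", {
  withr::with_seed(7, {
    for (i in 1:100) {
      n <- sample(4:26, 1)
      phy <- random_unrooted_tree(n)
      phy$edge.length <- signif(phy$edge.length, 6)
      nwk <- write_newick(phy)
      back <- parse_newick(nwk)
      expect_equal(rf_distance(phy, back), 0)
      expect_identical(write_newick(back), nwk)
    }
  })
  # supports survive the round trip
  t <- parse_newick("(((A:1,B:2)99:0.25,C:1)42:1,D:3,E:1);")
  expect_identical(write_newick(parse_newick(write_newick(t))), write_newick(t))
})

test_that("bipartition sets respect size and support filters", {
  expect_equal(nrow(bipartition_set(parse_newick("((A,B),C);"))), 0L)
  bal8 <- parse_newick("(((A,B),(C,D)),((E,F),(G,H)));")
  expect_equal(nrow(bipartition_set(bal8)), 5L)  # n - 3 internal edges
  filt <- bipartition_set(parse_newick("(A,B,(C,D)40);"), min_support = 50)
  expect_equal(nrow(filt), 0L)
  kept <- bipartition_set(parse_newick("(A,B,(C,D)60);"), min_support = 50)
  expect_equal(kept$split, "A,B|C,D")
})

test_that("rf_distance matches a brute-force split oracle on random pairs", {
  expect_equal(rf_distance(parse_newick("((A,B),C,(D,E));"),
                           parse_newick("((A,C),B,(D,E));")), 2)
  withr::with_seed(11, {
    for (i in 1:1000) {
      a <- random_unrooted_tree(8)
      b <- random_unrooted_tree(8)
      expect_identical(rf_distance(a, b), brute_rf(a, b))
    }
    t <- random_unrooted_tree(8)
    expect_identical(rf_distance(t, t), 0L)
  })
})

test_that("rf_distance agrees with phangorn on random pairs", {
  skip_if_not_installed("phangorn")
  withr::with_seed(13, {
    for (i in 1:50) {
      a <- random_unrooted_tree(10)
      b <- random_unrooted_tree(10)
      expect_equal(rf_distance(a, b), as.integer(phangorn::RF.dist(a, b)))
    }
  })
})

test_that("rf_distance rejects unequal taxon sets naming the asymmetry", {
  a <- parse_newick("((A,B),(C,D));")
  b <- parse_newick("((A,B),(C,E));")
  expect_error(rf_distance(a, b), "D")
  expect_error(rf_distance(a, b), "E")
})

test_that("restriction prunes, merges lengths and keeps minimum support", {
  cat5 <- parse_newick("((((A,B),C),D),E);")
  two <- restrict_to_taxa(cat5, c("A", "B"))
  expect_equal(sort(two$tip.label), c("A", "B"))

  r <- restrict_to_taxa(parse_newick("((A,B),(C,D),(E,F));"), c("A", "C", "E", "F"))
  expect_equal(write_newick(r), "(A,C,(E,F));")

  full <- restrict_to_taxa(cat5, cat5$tip.label)
  expect_equal(rf_distance(full, cat5), 0)

  # suppressed degree-2 nodes: lengths add, supports take the minimum
  t <- parse_newick("((((A:1,B:1)30:2,C:1)80:4,D:1)70:1,(E:1,F:1)95:1);")
  r2 <- restrict_to_taxa(t, c("A", "B", "D", "E", "F"))
  bs <- bipartition_set(r2)
  expect_equal(bs$support[bs$split == "A,B|D,E,F"], 30)
  ab_len <- bs$length[bs$split == "A,B|D,E,F"]
  expect_equal(ab_len, 2 + 4)  # merged edge lengths add

  expect_error(restrict_to_taxa(cat5, c("A", "Z")), "unknown")
})

test_that("induced topologies read quartets and rooted triples", {
  expect_equal(induced_topology(parse_newick("((A,B),C);"), c("A", "B", "C"),
                                rooted = TRUE), "A,B")
  expect_equal(induced_topology(parse_newick("(A,B,(C,(D,E)));"),
                                c("A", "B", "D", "E")), "A,B|D,E")
  star <- parse_newick("(A,B,C,D);")
  expect_equal(induced_topology(star, c("A", "B", "C", "D")), "unresolved")
  star3 <- parse_newick("((A,B,C),O);")
  expect_equal(induced_topology(star3, c("A", "B", "C"), rooted = TRUE),
               "unresolved")
  expect_error(induced_topology(parse_newick("(A,B,(C,D));"),
                                c("A", "B", "C"), rooted = TRUE), "rooted")
})

test_that("induced quartets equal restriction followed by split reading", {
  withr::with_seed(17, {
    for (i in 1:25) {
      phy <- random_unrooted_tree(9)
      taxa <- sort(sample(phy$tip.label, 4))
      via_restrict <- bipartition_set(restrict_to_taxa(phy, taxa))
      direct <- induced_topology(phy, taxa)
      if (nrow(via_restrict) == 0L) {
        expect_equal(direct, "unresolved")
      } else {
        expect_equal(direct, via_restrict$split[1])
      }
    }
  })
})

test_that("majority consensus counts splits strictly above the threshold", {
  t1 <- parse_newick("((A,B),(C,(D,E)));")
  forty <- rep(list(t1), 40)
  cons <- majority_consensus(forty, 0.5)
  expect_equal(rf_distance(cons, t1), 0)
  expect_true(all(cons$support[!is.na(cons$support)] == 100))

  # {AB|CDE x3, AC|BDE x1}: only the majority split is retained, at 75
  trees <- list(parse_newick("((A,B),(C,(D,E)));"),
                parse_newick("((A,B),(C,(D,E)));"),
                parse_newick("((A,B),(D,(C,E)));"),
                parse_newick("((A,C),(B,(D,E)));"))
  cons2 <- majority_consensus(trees, 0.5)
  bs <- bipartition_set(cons2)
  expect_true("A,B|C,D,E" %in% bs$split)
  expect_equal(bs$support[bs$split == "A,B|C,D,E"], 75)
  expect_false("A,C|B,D,E" %in% bs$split)

  # total disagreement on every split collapses to a star
  s1 <- parse_newick("((A,B),(C,D),E);")
  s2 <- parse_newick("((A,C),(B,D),E);")
  expect_equal(nrow(bipartition_set(majority_consensus(list(s1, s2), 0.5))), 0L)

  expect_error(majority_consensus(list(t1, parse_newick("((A,B),(C,F));"))),
               "mixed")
})

test_that("rerooting on an outgroup keeps the unrooted bipartitions", {
  t <- parse_newick("(A,B,((C,D)88,E));")
  for (x in t$tip.label) {
    rr <- reroot(t, x)
    expect_true(ape::is.rooted(rr))
    expect_equal(rf_distance(rr, t), 0)
  }
  rr <- reroot(t, "A")
  # root separates the outgroup from everything else
  ct_root_kids <- rr$edge[rr$edge[, 1] == ape::Ntip(rr) + 1L, 2]
  expect_true(which(rr$tip.label == "A") %in% ct_root_kids)
  # support values travel with their edges
  bs <- bipartition_set(rr)
  expect_equal(bs$support[bs$split == "A,B,E|C,D"], 88)
  # idempotent
  expect_identical(write_newick(reroot(rr, "A")), write_newick(rr))
  expect_error(reroot(t, "Z"), "unknown")
})

test_that("gene-tree files round-trip and skip comment lines", {
  trees <- withr::with_seed(3, lapply(1:5, function(i) random_unrooted_tree(6)))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_gene_trees(trees, path)
  lines <- readLines(path)
  writeLines(c("# a comment", lines[1:2], "", lines[3:5]), path)
  back <- read_gene_trees(path)
  expect_length(back, 5L)
  expect_equal(mapply(rf_distance, trees, back), rep(0L, 5))
})
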