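test_that("yule species trees are deterministic with exponential internals", {
  expect_error(sample_yule_species_tree(2), ">= 3")
  t3 <- sample_yule_species_tree(3, 1, seed = 1)
  expect_equal(ape::Ntip(t3), 3L)
  expect_true(ape::is.rooted(t3) && ape::is.binary(t3))

  a <- sample_yule_species_tree(12, 0.8, seed = 42)
  b <- sample_yule_species_tree(12, 0.8, seed = 42)
  expect_identical(write_newick(a), write_newick(b))

  # mean of sampled internal lengths matches the exponential moment
  lens <- unlist(lapply(1:1500, function(i) {
    tr <- sample_yule_species_tree(10, 0.7, seed = i)
    tr$edge.length[tr$edge[, 2] > ape::Ntip(tr)]
  }))
  expect_gt(length(lens), 10000)
  se <- 0.7 / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 0.7), 3 * se)
})

test_that("MSC triple frequencies follow 1 - (2/3) exp(-t)", {
  for (t in c(0, 0.5, 1, 2)) {
    sp <- parse_newick(sprintf("((A:1,B:1):%g,C:%g);", t, 1 + t))
    n <- 20000
    sims <- simulate_msc_gene_trees(sp, n, seed = 100 + round(10 * t))
    res <- vapply(sims, induced_topology, "", taxa = c("A", "B", "C"),
                  rooted = TRUE)
    p_expect <- 1 - (2 / 3) * exp(-t)
    se <- sqrt(p_expect * (1 - p_expect) / n)
    expect_lt(abs(mean(res == "A,B") - p_expect), 3 * se + 1e-9)
  }
  # no-ILS limit: long branch gives concordance ~ 1
  spL <- parse_newick("((A:1,B:1):50,C:51);")
  simsL <- simulate_msc_gene_trees(spL, 2000, seed = 9)
  expect_equal(mean(vapply(simsL, induced_topology, "", taxa = c("A", "B", "C"),
                           rooted = TRUE) == "A,B"), 1)
})

test_that("MSC simulation is deterministic and exchangeable under relabelling", {
  sp <- fixture_species_tree()
  a <- simulate_msc_gene_trees(sp, 25, seed = 5)
  b <- simulate_msc_gene_trees(sp, 25, seed = 5)
  expect_identical(vapply(a, write_newick, ""), vapply(b, write_newick, ""))

  # permuting tip labels of the guide tree permutes the simulated trees
  perm <- sp
  map <- c(A = "B", B = "A")
  perm$tip.label <- ifelse(perm$tip.label %in% names(map),
                           map[perm$tip.label], perm$tip.label)
  pa <- simulate_msc_gene_trees(perm, 200, seed = 6)
  aa <- simulate_msc_gene_trees(sp, 200, seed = 6)
  relabel <- function(tr) {
    tr$tip.label <- ifelse(tr$tip.label %in% names(map), map[tr$tip.label],
                           tr$tip.label)
    tr
  }
  expect_equal(sort(vapply(pa, write_newick, "")),
               sort(vapply(lapply(aa, relabel), write_newick, "")))
})

test_that("network gene trees mix displayed trees with probability gamma", {
  nm <- fixture_network(gamma = 0.45, tau = 0.5)
  sim <- simulate_network_gene_trees(nm, 10000, seed = 3)
  frac <- mean(sim$parent[, 1] == "minor")
  expect_lt(abs(frac - 0.45), 3 * sqrt(0.45 * 0.55 / 10000))

  # gamma = 0: distribution indistinguishable from MSC on the base tree
  nm0 <- fixture_network(gamma = 0, tau = 0.5)
  s0 <- simulate_network_gene_trees(nm0, 2000, seed = 4)
  expect_true(all(s0$parent == "major"))
  base_sims <- simulate_msc_gene_trees(nm0$base, 2000, seed = 5)
  rf0 <- rf_distribution(nm0$base, s0$trees)$values
  rfb <- rf_distribution(nm0$base, base_sims)$values
  expect_gt(suppressWarnings(stats::ks.test(rf0, rfb)$p.value), 0.01)

  # gamma = 1: identical in law to MSC on the minor displayed tree
  nm1 <- fixture_network(gamma = 1, tau = 0.5)
  s1 <- simulate_network_gene_trees(nm1, 500, seed = 6)
  expect_true(all(s1$parent == "minor"))
})

test_that("network models reject cycles and invalid parameters", {
  sp <- fixture_species_tree()
  expect_error(network_model(sp, recipient = c("F", "G"), donor = "F"),
               "cycle")
  expect_error(network_model(sp, recipient = "A", donor = "A"), "distinct")
  expect_error(network_model(sp, recipient = "A", donor = "B", gamma = 1.2),
               "gamma")
  expect_error(network_model(sp, recipient = "A", donor = c("A", "C")),
               "clade")
})

test_that("NNI noise perturbs topologies at the expected rate", {
  sp <- fixture_species_tree()
  genes <- simulate_msc_gene_trees(sp, 100, seed = 11)

  clean <- perturb_gene_trees(genes, sim_config(seed = 1, nni_noise_prob = 0,
                                                missing_prob = 0))
  expect_true(all(mapply(function(a, b) rf_distance(ape::unroot(a), b) == 0,
                         genes, clean)))
  sups <- unlist(lapply(clean, function(x) x$support[!is.na(x$support)]))
  expect_true(all(sups >= 80))

  # a forced rearrangement of the single internal edge of a quartet moves
  # to one of the two alternatives 2/3 of the time
  q <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  qs <- rep(list(q), 3000)
  pq <- perturb_gene_trees(qs, sim_config(seed = 9, nni_noise_prob = 1))
  moved <- mean(vapply(pq, function(x) rf_distance(x, ape::unroot(q)) > 0, TRUE))
  expect_lt(abs(moved - 2 / 3), 3 * sqrt(2 / 9 / 3000))

  # expected RF to the input grows with the noise rate
  mean_rf <- vapply(c(0, 0.05, 0.2), function(p) {
    per <- perturb_gene_trees(genes, sim_config(seed = 2, nni_noise_prob = p))
    mean(mapply(function(a, b) rf_distance(ape::unroot(a), b), genes, per))
  }, 0)
  expect_true(all(diff(mean_rf) > 0))

  # perturbed edges get low supports, untouched edges high supports
  noisy <- perturb_gene_trees(genes, sim_config(seed = 3, nni_noise_prob = 0.3))
  sups <- unlist(lapply(noisy, function(x) x$support[!is.na(x$support)]))
  expect_true(all(sups <= 49 | sups >= 80))
  expect_true(any(sups <= 49) && any(sups >= 80))

  # missing taxa are dropped at the configured rate
  miss <- perturb_gene_trees(genes, sim_config(seed = 4, nni_noise_prob = 0,
                                               missing_prob = 0.2))
  kept <- mean(vapply(miss, ape::Ntip, 1L))
  expect_lt(abs(kept - 9 * 0.8), 0.5)
})

test_that("generate_dataset writes a reproducible bundle", {
  cfg <- sim_config(seed = 21, n_genes = 60, nni_noise_prob = 0.05,
                    missing_prob = 0.05)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  nm <- fixture_network(gamma = 0.5, tau = 0.5)
  generate_dataset(nm, cfg, d1)
  generate_dataset(nm, cfg, d2)
  for (f in c("gene_trees.nwk", "true_species_tree.nwk", "true_network.txt",
              "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_length(readLines(file.path(d1, "gene_trees.nwk")), 60L)

  # bundle feeds the downstream stages without error
  gt <- read_gene_trees(file.path(d1, "gene_trees.nwk"))
  sp <- parse_newick(readLines(file.path(d1, "true_species_tree.nwk")))
  expect_s3_class(map_concordance(sp, gt), "node_conflict_summary")
  net <- read_network_model(file.path(d1, "true_network.txt"))
  expect_s3_class(net, "network_model")
  expect_equal(net$reticulations[[1]]$gamma, 0.5)
})
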