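test_that("rooted-triple counts classify resolutions and polytomies", {
  tr <- parse_newick("((((A,B),C),D),O);")
  tc <- count_rooted_triples(rep(list(tr), 7), "O")
  expect_s3_class(tc, "triple_counts")
  abc <- tc[tc$t1 == "A" & tc$t2 == "B" & tc$t3 == "C", ]
  expect_equal(abc$n12, 7L)
  expect_equal(abc$n13 + abc$n23 + abc$unresolved, 0L)

  star <- parse_newick("((A,B,C,D),O);")
  tc2 <- count_rooted_triples(rep(list(star), 3), "O")
  expect_true(all(tc2$unresolved == 3L))
  expect_true(all(tc2$n12 + tc2$n13 + tc2$n23 == 0L))

  expect_error(count_rooted_triples(list(tr), "Z"), "outgroup")

  # trees lacking the outgroup or a triple's taxa skip those counts
  tc3 <- count_rooted_triples(list(tr, parse_newick("((A,B),(C,D));")), "O")
  expect_true(all(tc3$n12 + tc3$n13 + tc3$n23 + tc3$unresolved <= 2L))
})

test_that("triple counts from MSC simulations match the closed form", {
  sp <- parse_newick("(((A:1,B:1):1,C:2):1,O:3);")
  sims <- simulate_msc_gene_trees(sp, 20000, seed = 81)
  tc <- count_rooted_triples(sims, "O")
  resolved <- tc$n12 + tc$n13 + tc$n23
  p <- tc$n12 / resolved
  p_exp <- 1 - (2 / 3) * exp(-1)
  expect_lt(abs(p - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / resolved))
})

test_that("expected triple probabilities are a valid gamma mixture", {
  nm <- fixture_network(gamma = 0.45, tau = 0.5)
  nm_in <- network_model(restrict_to_taxa(nm$base, setdiff(tree_taxa(nm$base), "O")),
                         recipient = "A", donor = c("F", "G"),
                         gamma = 0.45, tau = 0.5)
  ep <- expected_triple_probs(nm_in)
  expect_equal(rowSums(as.matrix(ep[, c("p12", "p13", "p23")])),
               rep(1, nrow(ep)), tolerance = 1e-9)

  # gamma = 0 and gamma = 1 collapse to the pure displayed trees (exact)
  e0 <- expected_triple_probs(nm_in, gamma = 0)
  base_probs <- expected_triple_probs(
    network_model(nm_in$base, recipient = "A", donor = c("F", "G"),
                  gamma = 0, tau = 0.5), gamma = 0)
  expect_equal(e0, base_probs)
  e1 <- expected_triple_probs(nm_in, gamma = 1, tau = 0.5)
  g05 <- expected_triple_probs(nm_in, gamma = 0.5, tau = 0.5)
  mix <- 0.5 * as.matrix(e1[, 4:6]) + 0.5 * as.matrix(e0[, 4:6])
  expect_equal(as.matrix(g05[, 4:6]), mix, tolerance = 1e-9)

  expect_error(expected_triple_probs(nm_in, gamma = 2), "gamma")
  expect_error(expected_triple_probs(nm_in, tau = -1), "tau")
})

test_that("expected probabilities agree with network simulations", {
  for (g in c(0.2, 0.5)) {
    for (tau in c(0.2, 1)) {
      nm <- fixture_network(gamma = g, tau = tau)
      sims <- simulate_network_gene_trees(nm, 6000,
                                          seed = round(1000 * g + 10 * tau))
      tc <- count_rooted_triples(sims$trees, "O")
      nm_in <- network_model(
        restrict_to_taxa(nm$base, setdiff(tree_taxa(nm$base), "O")),
        recipient = "A", donor = c("F", "G"), gamma = g, tau = tau)
      ep <- expected_triple_probs(nm_in)
      N <- as.matrix(tc[, c("n12", "n13", "n23")])
      P <- as.matrix(ep[, c("p12", "p13", "p23")])
      res <- rowSums(N)
      phat <- N / res
      se <- sqrt(P * (1 - P) / res)
      expect_true(all(abs(phat - P) < 3 * se + 0.02))
    }
  }
})

test_that("gamma is recovered from noise-free gene trees", {
  sp <- fixture_species_tree()
  bin <- restrict_to_taxa(sp, setdiff(tree_taxa(sp), "O"))
  for (g in c(0.2, 0.45, 0.5)) {
    sims <- simulate_network_gene_trees(fixture_network(g, 0.5), 2000,
                                        seed = round(100 * g))
    tc <- count_rooted_triples(sims$trees, "O")
    fit <- fit_single_reticulation(tc, bin,
                                   list(recipient = "A", donor = c("F", "G")))
    expect_lt(abs(fit$gamma - g), 0.05)
    expect_equal(fit$gamma + fit$gamma_major, 1)
    expect_gte(fit$logpl, fit$null_logpl)
  }
})

test_that("gamma recovery degrades gracefully under NNI noise", {
  sp <- fixture_species_tree()
  bin <- restrict_to_taxa(sp, setdiff(tree_taxa(sp), "O"))
  sims <- simulate_network_gene_trees(fixture_network(0.45, 0.5), 2000,
                                      seed = 91)
  noisy <- perturb_gene_trees(sims$trees,
                              sim_config(seed = 91, nni_noise_prob = 0.05))
  fit <- fit_single_reticulation(count_rooted_triples(noisy, "O"), bin,
                                 list(recipient = "A", donor = c("F", "G")))
  expect_lt(abs(fit$gamma - 0.45), 0.1)
})

test_that("boundary and null fits behave as expected", {
  sp <- fixture_species_tree()
  bin <- restrict_to_taxa(sp, setdiff(tree_taxa(sp), "O"))
  cand <- list(recipient = "A", donor = c("F", "G"))

  s1 <- simulate_network_gene_trees(fixture_network(1, 0.5), 2000, seed = 92)
  f1 <- fit_single_reticulation(count_rooted_triples(s1$trees, "O"), bin, cand)
  expect_gte(f1$gamma, 0.9)

  s0 <- simulate_msc_gene_trees(sp, 2000, seed = 93)
  f0 <- fit_single_reticulation(count_rooted_triples(s0, "O"), bin, cand)
  expect_true(f0$gamma <= 0.1 ||
                f0$logpl - f0$null_logpl < 0.01 * abs(f0$null_logpl))

  empty <- count_rooted_triples(list(parse_newick("((A,B,C,D,E,F,G,H),O);")), "O")
  expect_error(fit_single_reticulation(empty, bin, cand), "zero resolved")
})

test_that("the candidate scan ranks the planted reticulation first", {
  sp <- fixture_species_tree()
  sims <- simulate_network_gene_trees(fixture_network(0.5, 0.5), 1500,
                                      seed = 95)
  scan <- scan_and_rank_networks(sims$trees, sp, "O", max_reticulations = 2)
  expect_equal(scan$table$recipient[1], "A")
  expect_equal(scan$table$donor[1], "F+G")
  expect_length(scan$retained, 1L)
  expect_s3_class(scan$selected, "network_model")
  expect_lt(abs(scan$retained[[1]]$gamma - 0.5), 0.07)

  # table is sorted non-increasing and every fit nests above the tree
  expect_true(all(diff(scan$table$logpl) <= 1e-9))
  expect_true(all(scan$table$logpl >= scan$null_logpl - 1e-6))
  expect_equal(nrow(scan$table), 160L)
})

test_that("tree-simulated data retain no reticulation", {
  sp <- fixture_species_tree()
  s0 <- simulate_msc_gene_trees(sp, 1500, seed = 96)
  scan <- scan_and_rank_networks(s0, sp, "O", max_reticulations = 2)
  expect_length(scan$retained, 0L)
  expect_null(scan$selected)
})
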