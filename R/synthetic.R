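#' @title Synthetic gene-tree data: species trees, MSC and network simulation
#' @description
#' Seeded generators emulating the statistical structure of
#' transcriptome-scale single-copy gene-tree sets: a species tree with
#' internal branch lengths in coalescent units (CU, 1 CU = 2N generations),
#' multispecies-coalescent (MSC) gene trees, gene flow through one or more
#' reticulations with inheritance probability gamma, and gene-tree
#' estimation error (per-edge NNI noise, bootstrap-like supports, missing
#' taxa).
#' @name synthetic_data
NULL

#' Sample a random species tree with coalescent-unit branch lengths
#'
#' Topology is a uniform coalescent shape; internal branch lengths are
#' i.i.d. exponential with mean `mean_internal_cu`; terminal branches are
#' set to 1 CU (they carry one lineage each and do not affect discordance).
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param mean_internal_cu Mean internal branch length in CU.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param taxa Optional taxon labels (default `s01`, `s02`, ...).
#' @return A rooted binary `phylo` tree with CU edge lengths.
#' @export
sample_yule_species_tree <- function(n_taxa, mean_internal_cu = 1, seed = 1,
                                     taxa = sprintf("s%02d", seq_len(n_taxa))) {
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  stopifnot(mean_internal_cu > 0, length(taxa) == n_taxa)
  with_seed(seed, {
    phy <- ape::rcoal(n_taxa, tip.label = taxa)
    ntip <- ape::Ntip(phy)
    internal <- phy$edge[, 2] > ntip
    phy$edge.length[internal] <- stats::rexp(sum(internal), rate = 1 / mean_internal_cu)
    phy$edge.length[!internal] <- 1.0
    phy$support <- rep(NA_real_, phy$Nnode)
    phy
  })
}

# Precomputed traversal data for the MSC simulator.
msc_prep <- function(model) {
  if (!ape::is.rooted(model)) stop("species tree must be rooted")
  if (!ape::is.binary(model)) stop("species tree must be binary")
  if (is.null(model$edge.length)) stop("species tree must have CU branch lengths")
  ntip <- ape::Ntip(model)
  nn <- ntip + model$Nnode
  tr <- stats::reorder(model, "postorder")
  elen <- rep(NA_real_, nn)
  kids <- vector("list", nn)
  for (r in seq_len(nrow(tr$edge))) {
    p <- tr$edge[r, 1]; c <- tr$edge[r, 2]
    elen[c] <- tr$edge.length[r]
    kids[[p]] <- c(kids[[p]], c)
  }
  root <- ntip + 1L
  # children-first node order: postorder edge child sequence, then root
  ord <- unique(c(tr$edge[, 2], root))
  age <- numeric(nn)
  for (v in ord) {
    if (v > ntip) age[v] <- max(age[kids[[v]]] + elen[kids[[v]]])
  }
  labels <- sort(tr$tip.label)
  tipgene <- match(tr$tip.label, labels)  # species node id -> gene tip id
  list(ntip = ntip, nodes = ord, kids = kids, elen = elen, age = age,
       root = root, labels = labels, tipgene = tipgene)
}

# One MSC gene tree; returns a rooted binary phylo over prep$labels.
msc_sim_one <- function(prep) {
  K <- prep$ntip
  merge_x <- integer(K - 1L); merge_y <- integer(K - 1L); merge_age <- numeric(K - 1L)
  lin_age <- numeric(2L * K - 1L)
  surv <- vector("list", K + length(prep$nodes))
  m <- 0L
  for (v in prep$nodes) {
    if (v <= K) {
      lins <- prep$tipgene[v]
    } else {
      lins <- unlist(surv[prep$kids[[v]]], use.names = FALSE)
    }
    L <- if (v == prep$root) Inf else prep$elen[v]
    base_age <- prep$age[v]
    t <- 0
    k <- length(lins)
    while (k >= 2L) {
      w <- stats::rexp(1L, rate = k * (k - 1L) / 2)
      if (t + w > L) break
      t <- t + w
      pr <- sample.int(k, 2L)
      m <- m + 1L
      id <- K + m
      merge_x[m] <- lins[pr[1]]; merge_y[m] <- lins[pr[2]]
      merge_age[m] <- base_age + t
      lin_age[id] <- base_age + t
      lins <- c(lins[-pr], id)
      k <- k - 1L
    }
    surv[[v]] <- lins
  }
  # phylo numbering: root (last merge) must be K+1
  id_map <- c(seq_len(K), K + (K - seq_len(K - 1L)))
  edge <- matrix(0L, 2L * (K - 1L), 2L)
  elen <- numeric(2L * (K - 1L))
  r <- 0L
  for (mm in seq_len(K - 1L)) {
    p <- id_map[K + mm]
    for (ch in c(merge_x[mm], merge_y[mm])) {
      r <- r + 1L
      edge[r, 1] <- p
      edge[r, 2] <- id_map[ch]
      elen[r] <- merge_age[mm] - lin_age[ch]
    }
  }
  # rows are appended children-before-parents, a valid postorder: callers
  # can accumulate clades over the rows directly without reordering
  structure(list(edge = edge, edge.length = elen, tip.label = prep$labels,
                 Nnode = K - 1L), class = "phylo", order = "postorder")
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Standard MSC on a rooted binary guide tree with branch lengths in
#' coalescent units: within a branch carrying k lineages, coalescence
#' waiting times are exponential with rate k(k-1)/2; lineages that fail to
#' coalesce pass rootward, and all remaining lineages coalesce above the
#' root.
#'
#' @param model Rooted binary `phylo` species tree with CU edge lengths.
#' @param n Number of independent gene trees.
#' @param seed Integer seed.
#' @return A list of `n` rooted binary gene trees.
#' @export
simulate_msc_gene_trees <- function(model, n, seed = 1) {
  prep <- msc_prep(model)
  with_seed(seed, lapply(seq_len(n), function(i) msc_sim_one(prep)))
}

#' Describe a one-or-more-reticulation network model
#'
#' A reticulation regrafts the clade below the recipient edge onto the
#' donor edge (entered at its midpoint, with `tau` extra CU of pendant
#' length) with probability `gamma` (the minor/donor-side inheritance
#' probability); with probability `1 - gamma` the gene follows the base
#' species tree.
#'
#' @param base Rooted binary `phylo` species tree with CU edge lengths.
#' @param recipient,donor Character vectors of tip labels naming the clade
#'   below the recipient/donor edge (a single label for a terminal edge).
#' @param gamma Inheritance probability of the minor (donor) edge, in \[0,1\].
#' @param tau Extra CU length on the regrafted attachment (>= 0).
#' @param reticulations Alternatively, a list of
#'   `list(recipient=, donor=, gamma=, tau=)` entries.
#' @return A `network_model` object.
#' @export
network_model <- function(base, recipient = NULL, donor = NULL, gamma = 0.5,
                          tau = 0.5, reticulations = NULL) {
  if (is.null(reticulations)) {
    reticulations <- list(list(recipient = recipient, donor = donor,
                               gamma = gamma, tau = tau))
  }
  taxa <- tree_taxa(base)
  ct <- clade_table(base)
  for (ret in reticulations) {
    rmask <- taxa_to_mask(ret$recipient, taxa)
    dmask <- taxa_to_mask(ret$donor, taxa)
    if (!(rmask %in% ct$mask)) stop("recipient is not a clade of the base tree")
    if (!(dmask %in% ct$mask)) stop("donor is not a clade of the base tree")
    if (rmask == dmask) stop("recipient and donor edges must be distinct")
    if (bitwAnd(dmask, bitwNot(rmask)) == 0L) {
      stop("donor edge lies inside the recipient clade (cycle)")
    }
    if (ret$gamma < 0 || ret$gamma > 1) stop("gamma must be in [0, 1]")
    if (ret$tau < 0) stop("tau must be >= 0")
  }
  structure(list(base = base, reticulations = reticulations),
            class = "network_model")
}

# Detach the clade with tip set `recipient` and reattach it onto the edge
# above the clade with tip set `donor`, entered at the edge midpoint, adding
# `tau` CU to the moved clade's pendant edge. Works on any displayed tree in
# which both clades still exist; returns NULL when they do not.
regraft_clade <- function(tree, recipient, donor, tau) {
  taxa <- tree_taxa(tree)
  rmask <- taxa_to_mask(intersect(recipient, taxa), taxa)
  dmask0 <- taxa_to_mask(intersect(donor, taxa), taxa)
  dmask <- bitwAnd(dmask0, bitwNot(rmask))
  if (popcount(rmask) == 0L || popcount(dmask) == 0L) return(NULL)
  moved <- NULL
  node_mask <- function(nd) taxa_to_mask(node_tips(nd), taxa)
  node_tips <- function(nd) {
    if (is.null(nd$children)) nd$label else unlist(lapply(nd$children, node_tips))
  }
  detach <- function(nd) {
    if (is.null(nd$children)) return(nd)
    masks <- vapply(nd$children, node_mask, 0L)
    hit <- which(masks == rmask)
    if (length(hit) == 1L) {
      moved <<- nd$children[[hit]]
      nd$children <- nd$children[-hit]
    } else {
      nd$children <- lapply(nd$children, detach)
    }
    if (length(nd$children) == 1L) {
      k <- nd$children[[1]]
      if (!is.na(nd$len)) k$len <- if (is.na(k$len)) nd$len else k$len + nd$len
      s <- c(k$support, nd$support)
      k$support <- if (all(is.na(s))) NA_real_ else min(s, na.rm = TRUE)
      return(k)
    }
    nd
  }
  attach_at <- function(nd) {
    if (node_mask(nd) == dmask && !is.na(nd$len)) {
      half <- nd$len / 2
      nd$len <- half
      moved2 <- moved
      moved2$len <- (if (is.na(moved2$len)) 0 else moved2$len) + tau
      return(list(label = NULL, len = half, support = NA_real_,
                  children = list(nd, moved2)))
    }
    if (!is.null(nd$children)) nd$children <- lapply(nd$children, attach_at)
    nd
  }
  root <- detach(as_node_list(tree))
  if (is.null(moved)) return(NULL)
  # donor edge may have become the root edge after detaching a root child;
  # attach at its midpoint and make a new root above it
  if (node_mask(root) == dmask) {
    half <- if (is.na(root$len)) 0 else root$len / 2
    root$len <- half
    moved2 <- moved
    moved2$len <- (if (is.na(moved2$len)) 0 else moved2$len) + tau
    root <- list(label = NULL, len = NA_real_, support = NA_real_,
                 children = list(root, moved2))
  } else {
    root$len <- NA_real_
    root <- attach_at(root)
  }
  # the donor may not be a clade of this tree (e.g. after earlier regrafts)
  if (node_mask(root) != taxa_to_mask(taxa, taxa)) return(NULL)
  node_list_to_phylo(root)
}

# Displayed tree of a network for a given minor/major choice per reticulation.
displayed_tree <- function(model, minor) {
  tr <- model$base
  for (i in seq_along(model$reticulations)) {
    if (!minor[i]) next
    ret <- model$reticulations[[i]]
    out <- regraft_clade(tr, ret$recipient, ret$donor, ret$tau)
    if (!is.null(out)) tr <- out
  }
  tr
}

#' Simulate gene trees from a reticulate (network) model
#'
#' Each gene resolves every reticulation independently: with probability
#' `gamma` it follows the minor (donor) displayed tree, otherwise the major
#' one; the resulting displayed species tree drives the MSC simulator.
#'
#' @param model A [network_model()].
#' @param n Number of gene trees.
#' @param seed Integer seed.
#' @return A list with `trees` (rooted gene trees) and `parent` (an
#'   `n x R` character matrix of `"major"`/`"minor"` labels, one column per
#'   reticulation).
#' @export
simulate_network_gene_trees <- function(model, n, seed = 1) {
  stopifnot(inherits(model, "network_model"))
  R <- length(model$reticulations)
  gammas <- vapply(model$reticulations, `[[`, 0, "gamma")
  minor <- with_seed(derive_seed(seed, "ret-choice"), {
    matrix(stats::runif(n * R) < rep(gammas, each = n), n, R)
  })
  combo <- apply(minor, 1, function(z) paste(as.integer(z), collapse = ""))
  trees <- vector("list", n)
  for (cb in unique(combo)) {
    idx <- which(combo == cb)
    z <- as.logical(as.integer(strsplit(cb, "")[[1]]))
    dt <- displayed_tree(model, z)
    trees[idx] <- simulate_msc_gene_trees(dt, length(idx),
                                          seed = derive_seed(seed, paste0("msc", cb)))
  }
  parent <- matrix(ifelse(minor, "minor", "major"), n, R)
  colnames(parent) <- paste0("reticulation", seq_len(R))
  list(trees = trees, parent = parent)
}

#' Simulation configuration for gene-tree estimation noise
#'
#' @param seed Integer master seed.
#' @param n_genes Number of gene trees.
#' @param nni_noise_prob Probability that each internal edge of a gene tree
#'   is NNI-rearranged (a rearrangement exchanges two of the four subtrees
#'   incident to the edge, chosen uniformly, so it leaves the topology
#'   unchanged with probability 1/3).
#' @param support_high,support_low Integer ranges (length-2 vectors) for
#'   supports on untouched and perturbed edges.
#' @param missing_prob Probability that each leaf is deleted.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_genes = 500, nni_noise_prob = 0.05,
                       support_high = c(80, 100), support_low = c(0, 49),
                       missing_prob = 0) {
  stopifnot(n_genes >= 1, nni_noise_prob >= 0, nni_noise_prob <= 1,
            missing_prob >= 0, missing_prob <= 1)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 nni_noise_prob = nni_noise_prob,
                 support_high = support_high, support_low = support_low,
                 missing_prob = missing_prob),
            class = "sim_config")
}

# Children rows of `node` in the edge matrix.
edge_rows_of <- function(edge, node) which(edge[, 1] == node)

# One NNI-style perturbation of the edge whose child end is internal node v:
# choice 0 keeps the topology, 1 and 2 produce the two alternative
# resolutions (swapping one of v's child subtrees with a sibling subtree).
nni_swap <- function(phy, v, choice) {
  if (choice == 0L) return(phy)
  edge <- phy$edge
  u <- edge[edge[, 2] == v, 1]
  rows_v <- edge_rows_of(edge, v)
  rows_u <- setdiff(edge_rows_of(edge, u), which(edge[, 2] == v))
  ra <- rows_v[choice]          # child subtree of v to move
  rc <- rows_u[1]               # first sibling subtree at u
  a <- edge[ra, 2]; c <- edge[rc, 2]
  edge[ra, 2] <- c
  edge[rc, 2] <- a
  phy$edge <- edge
  phy
}

# Internal non-root nodes, i.e. child ends of internal edges.
internal_edge_children <- function(phy) {
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  v <- phy$edge[, 2]
  sort(v[v > ntip & v != root])
}

#' Add estimation noise to gene trees
#'
#' Unroots each tree, NNI-perturbs each internal edge independently with
#' probability `nni_noise_prob`, assigns supports (perturbed edges from the
#' low range, untouched edges from the high range) and deletes leaves with
#' probability `missing_prob` (deletion is skipped when fewer than 4 leaves
#' would remain). Deterministic given `config$seed`.
#'
#' @param trees List of binary gene trees.
#' @param config A [sim_config()].
#' @return List of unrooted gene trees with supports.
#' @export
perturb_gene_trees <- function(trees, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "perturb"), {
    lapply(trees, function(tr) {
      phy <- if (ape::is.rooted(tr)) ape::unroot(tr) else tr
      phy$support <- NULL
      ntip <- ape::Ntip(phy)
      verts <- internal_edge_children(phy)
      hit <- stats::runif(length(verts)) < config$nni_noise_prob
      perturbed <- logical(phy$Nnode)
      for (i in seq_along(verts)) {
        if (!hit[i]) next
        choice <- sample.int(3L, 1L) - 1L  # 0 = unchanged, 1/2 = alternatives
        phy <- nni_swap(phy, verts[i], choice)
        perturbed[verts[i] - ntip] <- TRUE
      }
      phy <- stats::reorder(phy, "cladewise")
      sup <- rep(NA_real_, phy$Nnode)
      for (v in internal_edge_children(phy)) {
        rng <- if (perturbed[v - ntip]) config$support_low else config$support_high
        sup[v - ntip] <- sample(seq(rng[1], rng[2]), 1L)
      }
      phy$support <- sup
      if (config$missing_prob > 0) {
        drop <- stats::runif(ntip) < config$missing_prob
        if (ntip - sum(drop) >= 4L && any(drop)) {
          phy <- restrict_to_taxa(phy, phy$tip.label[!drop])
        }
      }
      phy
    })
  })
}

#' Write a network model as structured text
#'
#' First line: base tree Newick; one line per reticulation in the form
#' `recipient=<tips>, donor=<tips>, gamma=<g>, tau=<t>`.
#' @param model A [network_model()].
#' @param path File path.
#' @export
write_network_model <- function(model, path) {
  lines <- write_newick(model$base)
  for (ret in model$reticulations) {
    lines <- c(lines, sprintf("recipient=%s, donor=%s, gamma=%s, tau=%s",
      paste(sort(ret$recipient), collapse = "+"),
      paste(sort(ret$donor), collapse = "+"),
      fmt_num(ret$gamma), fmt_num(ret$tau)))
  }
  writeLines(lines, path)
}

#' Read a network model from structured text
#' @param path File path written by [write_network_model()].
#' @return A [network_model()].
#' @export
read_network_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  base <- parse_newick(lines[1])
  rets <- lapply(lines[-1][nzchar(lines[-1])], function(ln) {
    kv <- strsplit(strsplit(ln, ",\\s*(?=[a-z]+=)", perl = TRUE)[[1]], "=")
    vals <- stats::setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
    list(recipient = strsplit(vals[["recipient"]], "+", fixed = TRUE)[[1]],
         donor = strsplit(vals[["donor"]], "+", fixed = TRUE)[[1]],
         gamma = as.numeric(vals[["gamma"]]), tau = as.numeric(vals[["tau"]]))
  })
  network_model(base, reticulations = rets)
}

#' Generate a reproducible gene-tree fixture bundle on disk
#'
#' Simulates gene trees from a species tree or network model, adds
#' estimation noise, and writes `gene_trees.nwk`, `true_species_tree.nwk`,
#' `true_network.txt` (network models only) and `manifest.json` (seeds,
#' parameters, per-gene parent labels). Re-running with the same inputs
#' reproduces byte-identical files.
#'
#' @param model A rooted species tree (`phylo`) or a [network_model()].
#' @param config A [sim_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return Invisibly, a list with the trees and the manifest.
#' @export
generate_dataset <- function(model, config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  is_net <- inherits(model, "network_model")
  base <- if (is_net) model$base else model
  if (is_net) {
    sim <- simulate_network_gene_trees(model, config$n_genes,
                                       seed = derive_seed(config$seed, "genes"))
    raw <- sim$trees
    parent <- sim$parent
  } else {
    raw <- simulate_msc_gene_trees(base, config$n_genes,
                                   seed = derive_seed(config$seed, "genes"))
    parent <- NULL
  }
  noisy <- perturb_gene_trees(raw, config)
  write_gene_trees(noisy, file.path(out_dir, "gene_trees.nwk"))
  writeLines(write_newick(base), file.path(out_dir, "true_species_tree.nwk"))
  if (is_net) write_network_model(model, file.path(out_dir, "true_network.txt"))
  manifest <- list(
    seed = config$seed,
    n_genes = config$n_genes,
    nni_noise_prob = config$nni_noise_prob,
    support_high = config$support_high,
    support_low = config$support_low,
    missing_prob = config$missing_prob,
    model_type = if (is_net) "network" else "species_tree",
    parent_labels = if (is_net) as.data.frame(parent) else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(list(trees = noisy, raw = raw, parent = parent, manifest = manifest))
}
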