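#' @title Species-tree estimation by quartet-score maximization
#' @description
#' The species-tree topology is the one maximizing the number of induced
#' four-taxon (quartet) agreements with the gene trees, the objective that
#' makes summary species-tree estimation statistically consistent under the
#' multispecies coalescent. Internal branch lengths in coalescent units are
#' recovered from quartet concordance frequencies around each branch via
#' the MSC closed form `p = 1 - (2/3) exp(-t)`.
#' @name speciestree
NULL

# All 4-taxon subsets of `taxa` as bitmasks, plus the per-quartet bit values
# needed to classify a resolution into one of three classes.
quartet_index <- function(n) {
  combs <- utils::combn(n, 4L)
  bits <- bitwShiftL(1L, combs - 1L)
  dim(bits) <- dim(combs)
  qmask <- bits[1, ] + bits[2, ] + bits[3, ] + bits[4, ]
  list(qmask = as.integer(qmask), b2 = as.integer(bits[2, ]),
       b3 = as.integer(bits[3, ]), b4 = as.integer(bits[4, ]))
}

# Classify pair masks (from quartet_pair_masks) into classes 0..3:
# 0 unresolved; 1/2/3 = lowest taxon paired with 2nd/3rd/4th taxon.
classify_pairs <- function(pm, qi, idx) {
  other <- pm - lowest_bit(qi$qmask[idx])
  cls <- integer(length(pm))
  cls[pm != 0L & other == qi$b2[idx]] <- 1L
  cls[pm != 0L & other == qi$b3[idx]] <- 2L
  cls[pm != 0L & other == qi$b4[idx]] <- 3L
  cls
}

# Aggregated quartet-resolution counts over the gene trees: a matrix
# [n_quartets x 3] of votes, computed once and reused across candidates.
quartet_vote_matrix <- function(gene_trees, master) {
  n <- length(master)
  qi <- quartet_index(n)
  votes <- matrix(0L, length(qi$qmask), 3L)
  genes <- gene_split_data(gene_trees, master)
  for (g in genes) {
    present <- which(bitwAnd(g$taxa_mask, qi$qmask) == qi$qmask)
    if (length(present) == 0L) next
    pm <- quartet_pair_masks(g$masks, qi$qmask[present])
    cls <- classify_pairs(pm, qi, present)
    for (k in 1:3) {
      hit <- present[cls == k]
      votes[hit, k] <- votes[hit, k] + 1L
    }
  }
  list(votes = votes, qi = qi)
}

# Resolution class of every quartet in a (binary) candidate tree.
candidate_classes <- function(candidate, master, qi) {
  st <- split_table(candidate)
  masks <- remap_masks(st$mask, tree_taxa(candidate), master)
  pm <- quartet_pair_masks(masks, qi$qmask)
  classify_pairs(pm, qi, seq_along(qi$qmask))
}

#' Quartet agreement score of a candidate species tree
#'
#' For every 4-taxon subset present in a gene tree, the candidate scores one
#' point when the gene tree's induced quartet split matches the candidate's
#' (exhaustive over all C(n,4) quartets and all genes). Optionally estimates
#' a per-branch quartet concordance fraction from sampled replicate draws.
#'
#' @param candidate Binary tree on all taxa appearing in the gene trees.
#' @param gene_trees List of gene trees (missing taxa allowed).
#' @param branch_draws Replicates per branch for the per-branch concordance
#'   fraction (0 to skip).
#' @param seed Seed for the branch draws.
#' @return A list with `score` (integer), `max_score` (resolved quartet
#'   votes available) and, when requested, `branch_pbar` (data frame of
#'   per-branch concordance fractions).
#' @export
quartet_score <- function(candidate, gene_trees, branch_draws = 0, seed = 1) {
  master <- tree_taxa(candidate)
  for (g in gene_trees) {
    extra <- setdiff(g$tip.label, master)
    if (length(extra) > 0L) {
      stop("candidate is missing taxa present in gene trees: ",
           paste(extra, collapse = ", "))
    }
  }
  qv <- quartet_vote_matrix(gene_trees, master)
  cls <- candidate_classes(candidate, master, qv$qi)
  score <- sum(qv$votes[cbind(seq_along(cls), cls)][cls > 0L])
  out <- list(score = score, max_score = sum(qv$votes))
  if (branch_draws > 0) {
    d <- branch_quartet_draws(candidate, gene_trees, branch_draws, seed)
    out$branch_pbar <- do.call(rbind, lapply(d, function(x) {
      res <- x[["t0"]] + x[["t1"]] + x[["t2"]]
      data.frame(branch = split_string(x[["split"]], master),
                 pbar = if (res > 0) x[["t0"]] / res else NA_real_,
                 resolved = res, stringsAsFactors = FALSE)
    }))
  }
  out
}

# The two NNI alternatives for every internal edge of an unrooted tree.
nni_neighbours <- function(phy) {
  out <- list()
  for (v in internal_edge_children(phy)) {
    for (choice in 1:2) {
      nb <- nni_swap(phy, v, choice)
      nb <- tryCatch(stats::reorder(nb, "cladewise"), error = function(e) NULL)
      if (!is.null(nb)) out[[length(out) + 1L]] <- nb
    }
  }
  out
}

#' Infer a species-tree topology from gene trees
#'
#' Starts from the majority consensus of the complete gene trees (polytomies
#' resolved at random but deterministically given `seed`) and hill-climbs
#' over NNI neighbours, accepting strict quartet-score improvements until a
#' local optimum; ties among equally best neighbours are broken by canonical
#' Newick order.
#'
#' @param gene_trees List of gene trees sharing >= 4 taxa.
#' @param seed Integer seed (used only to resolve consensus polytomies).
#' @return An unrooted binary tree.
#' @export
infer_species_tree <- function(gene_trees, seed = 1) {
  taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  if (length(taxa) < 4L) stop("need at least 4 shared taxa")
  complete <- Filter(function(g) setequal(g$tip.label, taxa), gene_trees)
  if (length(complete) == 0L) {
    stop("no gene tree carries the full taxon set; cannot seed the search")
  }
  start <- majority_consensus(complete, 0.5)
  start <- with_seed(seed, ape::multi2di(start, random = TRUE))
  cur <- ape::unroot(start)
  cur$support <- NULL
  qv <- quartet_vote_matrix(gene_trees, taxa)
  score_of <- function(tr) {
    cls <- candidate_classes(tr, taxa, qv$qi)
    sum(qv$votes[cbind(seq_along(cls), cls)][cls > 0L])
  }
  cur_score <- score_of(cur)
  repeat {
    nbs <- nni_neighbours(cur)
    if (length(nbs) == 0L) break
    scores <- vapply(nbs, score_of, 0)
    best <- max(scores)
    if (best <= cur_score) break
    cand <- nbs[scores == best]
    nwk <- vapply(cand, write_newick, "")
    cur <- cand[[order(nwk)[1]]]
    cur_score <- best
  }
  cur
}

#' Estimate coalescent-unit branch lengths on a fixed species tree
#'
#' Around each internal branch, the concordant fraction `p` of sampled
#' informative quartet draws is inverted through the MSC closed form
#' `T = -log((3/2) (1 - p))`, clamped to 0 when `p <= 1/3` and capped at 10
#' CU (discordance below Monte-Carlo resolution). Terminal branches are set
#' to 1 CU; branches with no informative draw get the cap with a warning.
#'
#' @param species_tree Rooted binary species tree (reroot first if needed;
#'   supply `outgroup` to have it done here).
#' @param gene_trees List of gene trees.
#' @param draws Quartet draws per branch (default 2000).
#' @param seed Integer seed.
#' @param outgroup Optional outgroup leaf used to root `species_tree`.
#' @param cap Maximum CU length (default 10).
#' @return The species tree with CU edge lengths; the per-branch table of
#'   (`pbar`, `t_hat`) is attached as attribute `"branch_estimates"`.
#' @export
estimate_coalescent_branch_lengths <- function(species_tree, gene_trees,
                                               draws = 2000, seed = 1,
                                               outgroup = NULL, cap = 10) {
  phy <- species_tree
  if (!is.null(outgroup)) phy <- reroot(phy, outgroup)
  if (!ape::is.rooted(phy)) stop("species tree must be rooted (or give an outgroup)")
  master <- tree_taxa(phy)
  n <- length(master)
  d <- branch_quartet_draws(phy, gene_trees, draws, seed)
  est <- lapply(d, function(x) {
    res <- x[["t0"]] + x[["t1"]] + x[["t2"]]
    pbar <- if (res > 0) x[["t0"]] / res else NA_real_
    t_hat <- if (is.na(pbar)) {
      NA_real_
    } else if (pbar <= 1 / 3) {
      0
    } else if (pbar >= 1 - (2 / 3) * exp(-cap)) {
      cap
    } else {
      -log(1.5 * (1 - pbar))
    }
    list(split = x[["split"]], pbar = pbar, t_hat = t_hat, resolved = res)
  })
  smap <- vapply(est, `[[`, 0L, "split")
  tvals <- vapply(est, `[[`, 0, "t_hat")
  if (anyNA(tvals)) {
    warning("branch(es) with no informative quartet draw; using the ", cap, " CU cap")
    tvals[is.na(tvals)] <- cap
  }
  ntip <- ape::Ntip(phy)
  ct <- clade_table(phy)
  root <- ntip + 1L
  root_children <- phy$edge[phy$edge[, 1] == root, 2]
  elen <- numeric(length(ct$child))
  for (r in seq_along(ct$child)) {
    child <- ct$child[r]
    if (!ct$internal[r]) { elen[r] <- 1.0; next }
    sm <- canonical_split(ct$mask[r], n)
    i <- match(sm, smap)
    if (is.na(i)) { elen[r] <- 1.0; next }  # trivial around the root
    elen[r] <- if (child %in% root_children && all(root_children > ntip)) {
      tvals[i] / 2  # the root split maps onto both root edges
    } else {
      tvals[i]
    }
  }
  # clade_table reordered edges; map back onto phy's edge order
  phy2 <- stats::reorder(phy, "postorder")
  phy2$edge.length <- elen
  out <- stats::reorder(phy2, "cladewise")
  out$support <- phy$support
  tab <- data.frame(branch = vapply(smap, split_string, "", taxa = master),
                    pbar = vapply(est, `[[`, 0, "pbar"),
                    t_hat = tvals,
                    resolved = vapply(est, `[[`, 0L, "resolved"),
                    stringsAsFactors = FALSE)
  attr(out, "branch_estimates") <- tab
  out
}
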