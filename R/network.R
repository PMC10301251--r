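#' @title Hybridization inference by rooted-triple pseudo-likelihood
#' @description
#' A reticulation with inheritance probability gamma makes each gene follow
#' the minor (donor) displayed tree with probability gamma and the major
#' (base) tree otherwise. Under the MSC, a rooted triple whose species-tree
#' internal path has CU length t resolves concordantly with probability
#' `1 - (2/3) exp(-t)` and each alternative with `(1/3) exp(-t)`; the
#' network's triple probabilities are the gamma-weighted mixture over
#' displayed trees. Fitting maximizes the multinomial pseudo-log-likelihood
#' of the observed triple counts over (gamma, tau).
#' @name network
NULL

# All 3-subsets of 1..n as bitmasks with the per-triple pair encodings.
triple_index <- function(n) {
  combs <- utils::combn(n, 3L)
  bits <- bitwShiftL(1L, combs - 1L)
  dim(bits) <- dim(combs)
  list(tmask = as.integer(bits[1, ] + bits[2, ] + bits[3, ]),
       p12 = as.integer(bits[1, ] + bits[2, ]),
       p13 = as.integer(bits[1, ] + bits[3, ]),
       p23 = as.integer(bits[2, ] + bits[3, ]),
       combs = combs)
}

#' Count rooted-triple resolutions across gene trees
#'
#' Each gene tree is rerooted on the outgroup and restricted to the focal
#' taxa; every triple whose three taxa are present contributes one count to
#' its observed resolution (or to `unresolved` at a polytomy). Trees
#' lacking the outgroup skip all triples.
#'
#' @param gene_trees List of gene trees.
#' @param outgroup Outgroup leaf label (excluded from the triples).
#' @param taxa Focal taxa (default: all non-outgroup taxa seen).
#' @return A `triple_counts` data frame: `t1 < t2 < t3`, counts `n12`,
#'   `n13`, `n23` (pair indicated by the suffix), `unresolved`; attributes
#'   `taxa` and `n_trees`.
#' @export
count_rooted_triples <- function(gene_trees, outgroup, taxa = NULL) {
  seen <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  if (!(outgroup %in% seen)) stop("outgroup absent from every gene tree")
  if (is.null(taxa)) taxa <- setdiff(seen, outgroup)
  taxa <- sort(taxa)
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 focal taxa")
  ti <- triple_index(n)
  nt <- length(ti$tmask)
  counts <- matrix(0L, nt, 4L)  # n12 n13 n23 unresolved
  for (g in gene_trees) {
    if (!(outgroup %in% g$tip.label)) next
    keep <- intersect(g$tip.label, taxa)
    if (length(keep) < 3L) next
    # clades of the outgroup-rooted tree are the og-free sides of the edges
    gt_all <- tree_taxa(g)
    ct <- clade_table(g)
    og_bit <- bitwShiftL(1L, match(outgroup, gt_all) - 1L)
    fm <- full_mask(length(gt_all))
    m <- ct$mask
    flip <- bitwAnd(m, og_bit) != 0L
    m[flip] <- bitwAnd(fm, bitwNot(m[flip]))
    cm <- remap_masks(m, gt_all, taxa)
    G <- taxa_to_mask(keep, taxa)
    present <- which(bitwAnd(G, ti$tmask) == ti$tmask)
    if (length(present) == 0L) next
    pm <- triple_pair_masks(cm, ti$tmask[present])
    col <- integer(length(present))
    col[pm == ti$p12[present]] <- 1L
    col[pm == ti$p13[present]] <- 2L
    col[pm == ti$p23[present]] <- 3L
    col[col == 0L] <- 4L
    for (k in 1:4) {
      hit <- present[col == k]
      counts[hit, k] <- counts[hit, k] + 1L
    }
  }
  out <- data.frame(t1 = taxa[ti$combs[1, ]], t2 = taxa[ti$combs[2, ]],
                    t3 = taxa[ti$combs[3, ]],
                    n12 = counts[, 1], n13 = counts[, 2], n23 = counts[, 3],
                    unresolved = counts[, 4], stringsAsFactors = FALSE)
  attr(out, "taxa") <- taxa
  attr(out, "n_trees") <- length(gene_trees)
  class(out) <- c("triple_counts", class(out))
  out
}

# Per-triple internal path lengths: a [n_triples x 3] matrix of t values,
# one column per pair (12, 13, 23); the pair that coalesces first in the
# tree has t > 0, the other two have t = 0.
triple_tvec <- function(tree, taxa) {
  n <- length(taxa)
  ti <- triple_index(n)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  depth <- numeric(nn)
  tr <- stats::reorder(tree, "cladewise")
  for (r in seq_len(nrow(tr$edge))) {
    depth[tr$edge[r, 2]] <- depth[tr$edge[r, 1]] + tr$edge.length[r]
  }
  gt <- tree_taxa(tree)
  ct <- clade_table(tr)
  cmask <- c(remap_masks(ct$mask, gt, taxa), taxa_to_mask(gt, taxa))
  cdepth <- c(depth[ct$child], 0)
  mrca_depth <- function(pm) {
    vapply(pm, function(p) max(cdepth[bitwAnd(cmask, p) == p]), 0)
  }
  d12 <- mrca_depth(ti$p12); d13 <- mrca_depth(ti$p13); d23 <- mrca_depth(ti$p23)
  dall <- mrca_depth(ti$tmask)
  cbind(d12 - dall, d13 - dall, d23 - dall)
}

# Mixture-free MSC triple probabilities from a t matrix.
probs_from_tvec <- function(tv) {
  am <- max.col(tv, ties.method = "first")
  tm <- tv[cbind(seq_len(nrow(tv)), am)]
  P <- matrix(exp(-tm) / 3, nrow(tv), 3L)
  P[cbind(seq_len(nrow(tv)), am)] <- P[cbind(seq_len(nrow(tv)), am)] + 1 - exp(-tm)
  P
}

#' Expected rooted-triple probabilities under a one-reticulation network
#'
#' Probabilities are computed per displayed tree from the MSC closed form
#' (concordant `1 - (2/3) exp(-t)`, each alternative `(1/3) exp(-t)`, with
#' t the CU path length between the triple's two internal nodes) and mixed
#' with weight `gamma` on the minor displayed tree.
#'
#' @param model A [network_model()] with a single (focal) reticulation.
#' @param gamma,tau Optional overrides of the model's values.
#' @return A data frame `t1,t2,t3,p12,p13,p23`; rows sum to 1.
#' @export
expected_triple_probs <- function(model, gamma = NULL, tau = NULL) {
  stopifnot(inherits(model, "network_model"))
  ret <- model$reticulations[[1]]
  gamma <- gamma %||% ret$gamma
  tau <- tau %||% ret$tau
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  if (tau < 0) stop("tau must be >= 0")
  taxa <- tree_taxa(model$base)
  ti <- triple_index(length(taxa))
  P_major <- probs_from_tvec(triple_tvec(model$base, taxa))
  minor <- regraft_clade(model$base, ret$recipient, ret$donor, tau)
  P_minor <- probs_from_tvec(triple_tvec(minor, taxa))
  P <- gamma * P_minor + (1 - gamma) * P_major
  data.frame(t1 = taxa[ti$combs[1, ]], t2 = taxa[ti$combs[2, ]],
             t3 = taxa[ti$combs[3, ]],
             p12 = P[, 1], p13 = P[, 2], p23 = P[, 3],
             stringsAsFactors = FALSE)
}

# t matrices of the minor displayed tree as linear functions of tau:
# t(tau) = A + B tau (B entries are 0 or 1: the path either crosses the
# regrafted attachment or not).
minor_linear_tvec <- function(base, recipient, donor, taxa) {
  m1 <- regraft_clade(base, recipient, donor, 1)
  m2 <- regraft_clade(base, recipient, donor, 2)
  if (is.null(m1) || is.null(m2)) return(NULL)
  t1 <- triple_tvec(m1, taxa)
  t2 <- triple_tvec(m2, taxa)
  list(A = pmax(2 * t1 - t2, 0), B = pmin(pmax(t2 - t1, 0), 1))
}

# Pseudo-log-likelihood machinery shared by the single fit and the greedy
# scan: `components` is a list of list(w, t_fixed, lin) where `lin` is NULL
# (candidate regraft impossible in that component) or minor_linear_tvec
# output. The mixture factorizes as gamma * M(tau) + (1 - gamma) * K with
# K constant, so K is precomputed and M evaluated once per tau.
mixture_pl <- function(N, components) {
  Pfix <- lapply(components, function(cp) probs_from_tvec(cp$t_fixed))
  K <- 0
  for (i in seq_along(components)) K <- K + components[[i]]$w * Pfix[[i]]
  M_of <- function(tau) {
    M <- 0
    for (i in seq_along(components)) {
      cp <- components[[i]]
      M <- M + cp$w * (if (is.null(cp$lin)) Pfix[[i]]
                       else probs_from_tvec(cp$lin$A + cp$lin$B * tau))
    }
    M
  }
  list(
    K = K,
    M_of = M_of,
    value = function(gamma, tau) {
      sum(N * log(gamma * M_of(tau) + (1 - gamma) * K))
    },
    value_g = function(gamma, M) sum(N * log(gamma * M + (1 - gamma) * K)),
    N = N
  )
}

maximize_pl <- function(pl, tau_max = 10, grid = 21, tol = 1e-4) {
  gs <- seq(0, 1, length.out = grid)
  ts <- seq(0, tau_max, length.out = grid)
  best <- list(gamma = 0, tau = 0, value = -Inf)
  for (tau in ts) {
    M <- pl$M_of(tau)
    for (g in gs) {
      v <- pl$value_g(g, M)
      if (v > best$value) best <- list(gamma = g, tau = tau, value = v)
    }
  }
  g <- best$gamma; tau <- best$tau
  for (round in 1:4) {
    M <- pl$M_of(tau)
    og <- stats::optimize(function(x) pl$value_g(x, M), c(0, 1),
                          maximum = TRUE, tol = tol)
    if (og$objective > best$value) { g <- og$maximum; best$value <- og$objective }
    ot <- stats::optimize(function(x) pl$value(g, x), c(0, tau_max),
                          maximum = TRUE, tol = tol)
    if (ot$objective > best$value) { tau <- ot$maximum; best$value <- ot$objective }
  }
  list(gamma = g, tau = tau, value = best$value)
}

#' Fit a single reticulation by maximum pseudo-likelihood
#'
#' Maximizes `PL(gamma, tau) = sum n log p(gamma, tau)` over the observed
#' rooted-triple counts, with a 21 x 21 grid scan over `gamma` in \[0,1\]
#' and `tau` in \[0, tau_max\] followed by coordinate-wise refinement
#' (tolerance 1e-4). All triples enter the sum, so fits are comparable
#' across candidates. Deterministic.
#'
#' @param counts A [count_rooted_triples()] table on the base tree's taxa.
#' @param base Rooted binary species tree with CU branch lengths (no
#'   outgroup).
#' @param candidate `list(recipient =, donor =)`, each a character vector of
#'   tip labels naming the clade below the edge.
#' @param tau_max,grid,tol Optimizer settings.
#' @return A `network_fit` list: `gamma` (minor/donor side), `gamma_major`,
#'   `tau`, `logpl`, `null_logpl` (base tree), and `expected` probabilities
#'   at the optimum.
#' @export
fit_single_reticulation <- function(counts, base, candidate, tau_max = 10,
                                    grid = 21, tol = 1e-4) {
  stopifnot(inherits(counts, "triple_counts"))
  taxa <- attr(counts, "taxa")
  if (!setequal(taxa, tree_taxa(base))) {
    stop("triple counts and base tree cover different taxa")
  }
  network_model(base, recipient = candidate$recipient, donor = candidate$donor,
                gamma = 0.5, tau = 1)  # validates the candidate (cycles etc.)
  N <- as.matrix(counts[, c("n12", "n13", "n23")])
  if (sum(N) == 0L) stop("zero resolved triples")
  t_base <- triple_tvec(base, taxa)
  lin <- minor_linear_tvec(base, candidate$recipient, candidate$donor, taxa)
  null_logpl <- sum(N * log(probs_from_tvec(t_base)))
  pl <- mixture_pl(N, list(list(w = 1, t_fixed = t_base, lin = lin)))
  opt <- maximize_pl(pl, tau_max = tau_max, grid = grid, tol = tol)
  P <- {
    Pmaj <- probs_from_tvec(t_base)
    Pmin <- if (is.null(lin)) Pmaj else probs_from_tvec(lin$A + lin$B * opt$tau)
    opt$gamma * Pmin + (1 - opt$gamma) * Pmaj
  }
  structure(list(
    recipient = sort(candidate$recipient), donor = sort(candidate$donor),
    gamma = opt$gamma, gamma_major = 1 - opt$gamma, tau = opt$tau,
    logpl = opt$value, null_logpl = null_logpl,
    expected = data.frame(counts[, c("t1", "t2", "t3")],
                          p12 = P[, 1], p13 = P[, 2], p23 = P[, 3])
  ), class = "network_fit")
}

# Candidate (recipient, donor) clade pairs of a rooted tree: every ordered
# pair of edges with the donor not inside the recipient clade.
candidate_pairs <- function(base) {
  taxa <- tree_taxa(base)
  ct <- clade_table(base)
  clades <- lapply(ct$mask, mask_to_taxa, taxa = taxa)
  out <- list()
  for (i in seq_along(clades)) {
    for (j in seq_along(clades)) {
      if (i == j) next
      rmask <- ct$mask[i]; dmask <- ct$mask[j]
      if (dmask == rmask) next
      if (bitwAnd(dmask, bitwNot(rmask)) == 0L) next  # donor inside recipient
      out[[length(out) + 1L]] <- list(recipient = clades[[i]], donor = clades[[j]])
    }
  }
  out
}

#' Enumerate, fit and rank single-reticulation candidates; build up a
#' network greedily
#'
#' Every valid (recipient edge, donor edge) pair on the base tree is fitted
#' by [fit_single_reticulation()] and ranked by pseudo-log-likelihood. The
#' best candidate is retained when it improves PL by at least
#' `improvement_threshold` (default 1 percent of |PL| of the tree); further
#' reticulations are added greedily with earlier ones frozen at their
#' fitted values, up to `max_reticulations`.
#'
#' @param gene_trees List of gene trees (with the outgroup).
#' @param base Rooted species tree with CU branch lengths, including the
#'   outgroup leaf.
#' @param outgroup Outgroup leaf label.
#' @param max_reticulations Maximum retained reticulations (default 5).
#' @param improvement_threshold Minimum PL gain to retain a reticulation.
#' @param tau_max Upper bound for the donor-attachment length.
#' @return A `network_scan` list: `table` (full ranked candidate table),
#'   `retained` fits, `selected` [network_model()] (or `NULL`),
#'   `null_logpl`, `threshold`.
#' @export
scan_and_rank_networks <- function(gene_trees, base, outgroup,
                                   max_reticulations = 5,
                                   improvement_threshold = NULL,
                                   tau_max = 10) {
  taxa_all <- tree_taxa(base)
  if (!(outgroup %in% taxa_all)) stop("outgroup not in base tree")
  ingroup <- setdiff(taxa_all, outgroup)
  if (length(ingroup) < 4L) stop("need at least 4 non-outgroup taxa")
  base_in <- restrict_to_taxa(base, ingroup)
  taxa <- tree_taxa(base_in)
  counts <- count_rooted_triples(gene_trees, outgroup, taxa = taxa)
  N <- as.matrix(counts[, c("n12", "n13", "n23")])
  t_base <- triple_tvec(base_in, taxa)
  null_logpl <- sum(N * log(probs_from_tvec(t_base)))
  thr <- improvement_threshold %||% (0.01 * abs(null_logpl))
  cands <- candidate_pairs(base_in)

  fit_round <- function(components, current_pl) {
    rows <- vector("list", length(cands))
    fits <- vector("list", length(cands))
    for (k in seq_along(cands)) {
      cd <- cands[[k]]
      comps <- lapply(components, function(cp) {
        cp$lin <- minor_linear_tvec(cp$tree, cd$recipient, cd$donor, taxa)
        cp
      })
      pl <- mixture_pl(N, comps)
      opt <- maximize_pl(pl, tau_max = tau_max)
      rows[[k]] <- data.frame(
        recipient = paste(sort(cd$recipient), collapse = "+"),
        donor = paste(sort(cd$donor), collapse = "+"),
        gamma = opt$gamma, tau = opt$tau, logpl = opt$value,
        delta = opt$value - current_pl, stringsAsFactors = FALSE)
      fits[[k]] <- c(cd, opt)
    }
    tab <- do.call(rbind, rows)
    ord <- order(-tab$logpl, tab$recipient, tab$donor)
    list(table = tab[ord, ], fits = fits[ord])
  }

  components <- list(list(w = 1, tree = base_in, t_fixed = t_base, lin = NULL))
  current_pl <- null_logpl
  retained <- list()
  first_table <- NULL
  repeat {
    rr <- fit_round(components, current_pl)
    if (is.null(first_table)) first_table <- rr$table
    best <- rr$fits[[1]]
    if (best$value - current_pl < thr || length(retained) >= max_reticulations) break
    retained[[length(retained) + 1L]] <- best
    current_pl <- best$value
    # expand displayed-tree components with the new, frozen reticulation
    components <- unlist(lapply(components, function(cp) {
      minor_tree <- regraft_clade(cp$tree, best$recipient, best$donor, best$tau)
      if (is.null(minor_tree)) return(list(cp))
      list(
        list(w = cp$w * (1 - best$gamma), tree = cp$tree, t_fixed = cp$t_fixed, lin = NULL),
        list(w = cp$w * best$gamma, tree = minor_tree,
             t_fixed = triple_tvec(minor_tree, taxa), lin = NULL)
      )
    }), recursive = FALSE)
    if (length(retained) >= max_reticulations) break
  }
  selected <- if (length(retained) > 0L) {
    network_model(base_in, reticulations = lapply(retained, function(f) {
      list(recipient = f$recipient, donor = f$donor, gamma = f$gamma, tau = f$tau)
    }))
  } else NULL
  rownames(first_table) <- NULL
  structure(list(table = first_table, retained = retained, selected = selected,
                 null_logpl = null_logpl, threshold = thr,
                 counts = counts, base = base_in),
            class = "network_scan")
}
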