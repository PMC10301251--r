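#' @title Gene-tree conflict: concordance mapping, ICA, quartet sampling
#' @name conflict
NULL

# Remap split masks from one taxon indexing to another; bits for taxa
# absent from `to_taxa` are dropped (restriction semantics).
remap_masks <- function(masks, from_taxa, to_taxa) {
  bitvals <- bitwShiftL(1L, match(from_taxa, to_taxa) - 1L)
  out <- integer(length(masks))
  for (j in seq_along(from_taxa)) {
    if (is.na(bitvals[j])) next
    has <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L
    out[has] <- bitwOr(out[has], bitvals[j])
  }
  out
}

lowest_bit <- function(x) bitwAnd(x, bitwNot(x - 1L))

# Per-gene split data in the master (species-tree) bit space.
gene_split_data <- function(gene_trees, master) {
  lapply(gene_trees, function(g) {
    gt <- tree_taxa(g)
    unknown <- setdiff(gt, master)
    if (length(unknown) > 0L) {
      stop("gene tree has taxa outside the species tree: ",
           paste(unknown, collapse = ", "))
    }
    st <- split_table(g)
    list(taxa_mask = taxa_to_mask(gt, master),
         ntaxa = length(gt),
         masks = remap_masks(st$mask, gt, master),
         support = st$support)
  })
}

#' Internode certainty (ICA) from observed bipartition counts
#'
#' The first element of `counts` is the reference bipartition; the rest are
#' its conflicting alternatives. Alternatives with relative frequency below
#' `prevalence` (among all counts considered) are discarded; frequencies are
#' renormalized over the retained set of size n and
#' `ICA = 1 + sum(p_i * log_n(p_i))`, negated when the reference does not
#' have the (weakly) largest retained count. A retained set of size 1 gives
#' ICA = 1.
#'
#' @param counts Non-negative counts, reference first; at least one > 0.
#' @param prevalence Relative-frequency threshold for alternatives.
#' @return ICA value in \[-1, 1\].
#' @export
compute_ica <- function(counts, prevalence = 0.05) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all counts are zero")
  ref <- counts[1]
  alts <- counts[-1]
  tot <- sum(counts)
  keep <- alts[alts / tot >= prevalence & alts > 0]
  ret <- c(ref, keep)
  n <- length(ret)
  if (n == 1L) return(1)
  p <- ret / sum(ret)
  p <- p[p > 0]
  mag <- 1 + sum(p * log(p) / log(n))
  if (ref >= max(keep)) mag else -mag
}

#' Map gene-tree concordance and conflict onto a species tree
#'
#' For each non-trivial species-tree bipartition B and each gene tree g:
#' if B restricted to g's taxa is trivial, g is counted *missing*; else if g
#' contains a bipartition identical to restricted-B that passes the support
#' filter, *concordant*; else if g contains a passing bipartition
#' incompatible with restricted-B, *conflicting* (one vote per gene, the
#' strongest-supported incompatible bipartition); otherwise *uninformative*.
#' Splits without a support annotation pass the filter; annotated splits
#' need support >= `min_support`.
#'
#' @param species_tree A `phylo` tree with >= 4 taxa.
#' @param gene_trees List of gene trees; taxa must be subsets of the
#'   species-tree taxa.
#' @param min_support Bootstrap filter (default 50).
#' @param prevalence Passed to [compute_ica()].
#' @return A data frame (one row per internal species-tree branch) with the
#'   five category counts and proportions, the top conflicting alternative,
#'   and ICA.
#' @export
map_concordance <- function(species_tree, gene_trees, min_support = 50,
                            prevalence = 0.05) {
  master <- tree_taxa(species_tree)
  nmaster <- length(master)
  fm <- full_mask(nmaster)
  sp <- split_table(species_tree)
  if (length(sp$mask) == 0L) stop("species tree has no internal branches")
  genes <- gene_split_data(gene_trees, master)
  ng <- length(gene_trees)

  rows <- lapply(sp$mask, function(B) {
    x_full <- B
    y_full <- bitwXor(fm, B)
    concord <- 0L; uninf <- 0L; miss <- 0L
    alt_keys <- character(0)
    for (g in genes) {
      G <- g$taxa_mask
      xg <- bitwAnd(x_full, G); yg <- bitwAnd(y_full, G)
      if (popcount(xg) < 2L || popcount(yg) < 2L) { miss <- miss + 1L; next }
      low <- lowest_bit(G)
      target <- if (bitwAnd(xg, low) == 0L) xg else yg
      pass <- is.na(g$support) | g$support >= min_support
      s <- g$masks[pass]
      sup <- g$support[pass]
      if (length(s) == 0L) { uninf <- uninf + 1L; next }
      sc <- bitwAnd(G, bitwNot(s))
      if (any(s == target)) { concord <- concord + 1L; next }
      inc <- popcount(bitwAnd(s, xg)) > 0L & popcount(bitwAnd(s, yg)) > 0L &
             popcount(bitwAnd(sc, xg)) > 0L & popcount(bitwAnd(sc, yg)) > 0L
      if (any(inc)) {
        si <- s[inc]
        supi <- sup[inc]
        supi[is.na(supi)] <- 100
        best <- si[which.max(supi)]
        b1 <- mask_to_taxa(best, master)
        b2 <- mask_to_taxa(bitwAnd(G, bitwNot(best)), master)
        if (min(b2) < min(b1)) { tmp <- b1; b1 <- b2; b2 <- tmp }
        alt_keys <- c(alt_keys,
                      paste(paste(b1, collapse = ","), paste(b2, collapse = ","), sep = "|"))
        next
      }
      uninf <- uninf + 1L
    }
    nconf <- length(alt_keys)
    if (nconf > 0L) {
      tab <- sort(table(alt_keys), decreasing = TRUE)
      top_names <- names(tab)[tab == max(tab)]
      top <- sort(top_names)[1]
      conf_top <- as.integer(tab[[top]])
      ica <- compute_ica(c(concord, as.integer(tab)), prevalence)
    } else {
      top <- NA_character_
      conf_top <- 0L
      ica <- if (concord + uninf + miss > 0L) 1 else NA_real_
    }
    data.frame(node = split_string(B, master),
               concordant = concord,
               conflict_top = conf_top,
               conflict_other = nconf - conf_top,
               uninformative = uninf,
               missing = miss,
               top_alternative = top,
               ica = ica,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (cn in c("concordant", "conflict_top", "conflict_other", "uninformative", "missing")) {
    out[[paste0("prop_", cn)]] <- out[[cn]] / ng
  }
  attr(out, "n_trees") <- ng
  attr(out, "taxa") <- master
  attr(out, "min_support") <- min_support
  attr(out, "masks") <- sp$mask
  class(out) <- c("node_conflict_summary", class(out))
  out
}

# The four taxon groups around each internal branch of a binary species
# tree (rooted, or unrooted with a basal trifurcation). Groups 1 and 2 are
# the two child subtrees of the branch's lower node; 3 and 4 subdivide the
# far side. Returns a list per branch: split mask and group index vectors.
branch_groups <- function(species_tree) {
  taxa <- tree_taxa(species_tree)
  n <- length(taxa)
  fm <- full_mask(n)
  ntip <- ape::Ntip(species_tree)
  root <- ntip + 1L
  ct <- clade_table(species_tree)
  cmask <- integer(ntip + species_tree$Nnode)
  cmask[ct$child] <- ct$mask
  cmask[root] <- fm
  edge <- stats::reorder(species_tree, "postorder")$edge
  parent_of <- integer(ntip + species_tree$Nnode)
  parent_of[edge[, 2]] <- edge[, 1]
  kids_of <- function(u) edge[edge[, 1] == u, 2]
  seen <- integer(0)
  out <- list()
  for (v in sort(unique(edge[, 2]))) {
    if (v <= ntip) next
    u <- parent_of[v]
    kv <- kids_of(v)
    if (length(kv) != 2L) next  # polytomy: skip
    A <- cmask[kv[1]]; B <- cmask[kv[2]]
    if (u == root) {
      others <- setdiff(kids_of(root), v)
      if (length(others) == 2L) {          # basal trifurcation
        C <- cmask[others[1]]; D <- cmask[others[2]]
      } else {                              # rooted binary root
        w <- others[1]
        if (w <= ntip) next                 # trivial unrooted edge
        kw <- kids_of(w)
        if (length(kw) != 2L) next
        C <- cmask[kw[1]]; D <- cmask[kw[2]]
      }
    } else {
      sibs <- setdiff(kids_of(u), v)
      if (length(sibs) != 1L) next
      C <- cmask[sibs[1]]
      D <- bitwAnd(fm, bitwNot(cmask[u]))
    }
    if (popcount(C) == 0L || popcount(D) == 0L) next
    sm <- canonical_split(cmask[v], n)
    if (popcount(sm) < 2L || popcount(sm) > n - 2L) next
    if (sm %in% seen) next
    seen <- c(seen, sm)
    out[[length(out) + 1L]] <- list(
      split = sm,
      groups = list(which(bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), A) != 0L),
                    which(bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), B) != 0L),
                    which(bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), C) != 0L),
                    which(bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), D) != 0L)))
  }
  out
}

# Quartet replicate draws around every internal branch: counts of the
# concordant (t0) and the two discordant resolutions (t1 = group-1 taxon
# with group-3 taxon, t2 = group-1 with group-4), plus uninformative (u).
branch_quartet_draws <- function(species_tree, gene_trees, replicates, seed) {
  master <- tree_taxa(species_tree)
  genes <- gene_split_data(gene_trees, master)
  brs <- branch_groups(species_tree)
  ng <- length(genes)
  with_seed(seed, {
    lapply(brs, function(br) {
      gi <- lapply(br$groups, function(g) {
        if (length(g) == 1L) rep(g, replicates) else sample(g, replicates, replace = TRUE)
      })
      gene_idx <- sample.int(ng, replicates, replace = TRUE)
      bit <- function(i) bitwShiftL(1L, i - 1L)
      ba <- bit(gi[[1]]); bb <- bit(gi[[2]]); bc <- bit(gi[[3]]); bd <- bit(gi[[4]])
      qmask <- bitwOr(bitwOr(ba, bb), bitwOr(bc, bd))
      res <- integer(replicates)  # 0 = uninformative, 1 = t0, 2 = t1, 3 = t2
      for (g in unique(gene_idx)) {
        sel <- which(gene_idx == g)
        gd <- genes[[g]]
        present <- bitwAnd(gd$taxa_mask, qmask[sel]) == qmask[sel]
        sel <- sel[present]
        if (length(sel) == 0L) next
        pm <- quartet_pair_masks(gd$masks, qmask[sel])
        low <- lowest_bit(qmask[sel])
        canon <- function(p) {
          flip <- bitwAnd(p, low) == 0L
          p[flip] <- bitwXor(qmask[sel][flip], p[flip])
          p
        }
        ab <- canon(bitwOr(ba[sel], bb[sel]))
        ac <- canon(bitwOr(ba[sel], bc[sel]))
        ad <- canon(bitwOr(ba[sel], bd[sel]))
        r <- integer(length(sel))
        r[pm != 0L & pm == ab] <- 1L
        r[pm != 0L & pm == ac] <- 2L
        r[pm != 0L & pm == ad] <- 3L
        res[sel] <- r
      }
      c(split = br$split, t0 = sum(res == 1L), t1 = sum(res == 2L),
        t2 = sum(res == 3L), u = sum(res == 0L))
    })
  })
}

#' Quartet-sampling branch support (QC/QD/QI)
#'
#' For each internal species-tree branch, each replicate draws one taxon
#' uniformly from each of the four subtrees the branch defines and one gene
#' tree uniformly, and reads the gene tree's induced quartet: concordant
#' (t0), one of the two discordant resolutions (t1/t2, anchored to the
#' branch's subtree groups), or uninformative (taxa missing or unresolved).
#' `QC = 1 + sum(p_i log3 p_i)` over the resolved frequencies, negated when
#' t0 is not the strict maximum; `QD = 1 - |t1 - t2|/(t1 + t2)` (`NA` when
#' no discordant replicate was seen, rendered "-"); `QI` is the resolved
#' fraction.
#'
#' @param species_tree Binary species tree with >= 4 taxa.
#' @param gene_trees List of gene trees (taxa subsets of the species tree).
#' @param replicates_per_branch Replicates per branch (default 1000).
#' @param seed Integer seed.
#' @return A data frame with one row per internal branch: `branch`,
#'   replicate counts `t0`, `t1`, `t2`, `u`, and `qc`, `qd`, `qi`.
#' @export
quartet_sampling <- function(species_tree, gene_trees,
                             replicates_per_branch = 1000, seed = 1) {
  if (length(tree_taxa(species_tree)) < 4L) stop("need at least 4 taxa")
  if (length(gene_trees) < 1L) stop("need at least one gene tree")
  master <- tree_taxa(species_tree)
  draws <- branch_quartet_draws(species_tree, gene_trees,
                                replicates_per_branch, seed)
  rows <- lapply(draws, function(d) {
    t0 <- d[["t0"]]; t1 <- d[["t1"]]; t2 <- d[["t2"]]; u <- d[["u"]]
    nres <- t0 + t1 + t2
    if (nres > 0L) {
      p <- c(t0, t1, t2) / nres
      p <- p[p > 0]
      mag <- 1 + sum(p * log(p) / log(3))
      qc <- if (t0 > max(t1, t2)) mag else -mag
    } else {
      qc <- NA_real_
    }
    qd <- if (t1 + t2 > 0L) 1 - abs(t1 - t2) / (t1 + t2) else NA_real_
    qi <- nres / (nres + u)
    data.frame(branch = split_string(d[["split"]], master),
               t0 = t0, t1 = t1, t2 = t2, u = u,
               qc = qc, qd = qd, qi = qi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- replicates_per_branch
  class(out) <- c("qs_scores", class(out))
  out
}

#' Write a per-node conflict table as TSV
#'
#' Columns: node bipartition, the five category counts and proportions, ICA
#' and (when `qs` is supplied) QC/QD/QI with undefined QD rendered `"-"`.
#' @param summary Output of [map_concordance()].
#' @param path File path.
#' @param qs Optional output of [quartet_sampling()] on the same tree.
#' @export
write_conflict_tsv <- function(summary, path, qs = NULL) {
  df <- as.data.frame(summary)
  if (!is.null(qs)) {
    m <- match(df$node, qs$branch)
    df$qc <- qs$qc[m]
    df$qd <- ifelse(is.na(qs$qd[m]), "-", fmt_num(qs$qd[m]))
    df$qi <- qs$qi[m]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Annotate a species tree with concordant/conflicting gene counts
#'
#' Internal node labels become `"<concordant>/<conflicting>"`, mirroring the
#' usual below-branch annotation of conflict analyses.
#' @param species_tree The species tree used in [map_concordance()].
#' @param summary Output of [map_concordance()].
#' @return A Newick string.
#' @export
conflict_annotated_newick <- function(species_tree, summary) {
  master <- tree_taxa(species_tree)
  n <- length(master)
  ntip <- ape::Ntip(species_tree)
  ct <- clade_table(species_tree)
  lab <- rep("", species_tree$Nnode)
  for (r in which(ct$internal)) {
    sm <- canonical_split(ct$mask[r], n)
    key <- split_string(sm, master)
    i <- match(key, summary$node)
    if (!is.na(i)) {
      lab[ct$child[r] - ntip] <- paste0(summary$concordant[i], "/",
        summary$conflict_top[i] + summary$conflict_other[i])
    }
  }
  phy <- species_tree
  phy$node.label <- lab
  phy$support <- NULL
  ape::write.tree(phy)
}
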