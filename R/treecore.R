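#' @title Tree substrate: Newick I/O, bipartitions, RF distance
#' @description
#' Trees are `ape` "phylo" objects carrying one extra field, `$support`: a
#' numeric vector of length `Nnode` with per-internal-node edge supports in
#' `[0, 100]` (`NA` where absent). The support of an internal node annotates
#' the edge between that node and its parent, the dominant convention of
#' maximum-likelihood tree files.
#' @name treecore
#' @importFrom ape read.tree is.rooted Ntip Nnode
NULL

tree_taxa <- function(tree) sort(tree$tip.label)

tree_support <- function(tree) {
  s <- tree$support
  if (is.null(s)) rep(NA_real_, tree$Nnode) else s
}

#' Parse a Newick string into a tree
#'
#' Internal node labels that read as numbers in \[0, 100\] become edge
#' supports under the default `"internal-node-label"` convention; under
#' `"comment"`, supports are taken from square-bracket comments following an
#' internal node (e.g. `"(A,B)[95]:0.5"`).
#'
#' @param text A single Newick statement ending in `";"`.
#' @param support_convention `"internal-node-label"` or `"comment"`.
#' @return A rooted or unrooted `phylo` tree with a `$support` field.
#' @export
parse_newick <- function(text, support_convention = c("internal-node-label", "comment")) {
  support_convention <- match.arg(support_convention)
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)

  # Structural pre-checks naming the character offset.
  chars <- charToRaw(text)
  depth <- cumsum((chars == charToRaw("(")) - (chars == charToRaw(")")))
  if (any(depth < 0L)) {
    stop("newick parse error: unbalanced ')' at offset ", which(depth < 0L)[1])
  }
  if (depth[length(depth)] != 0L) {
    stop("newick parse error: ", depth[length(depth)],
         " unclosed '(' at offset ", length(chars))
  }
  if (!endsWith(text, ";")) stop("newick parse error: missing ';' at offset ", nchar(text))

  if (support_convention == "comment") {
    # Lift ")[x]" comments into internal-node-label position, then parse.
    text <- gsub("\\)\\[([0-9eE.+-]+)\\]", ")\\1", text)
  }

  tr <- tryCatch(ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("newick parse error: ", conditionMessage(w)))
  if (is.null(tr)) stop("newick parse error: unreadable statement")

  if (any(!nzchar(tr$tip.label))) stop("newick parse error: empty taxon label")
  if (anyDuplicated(tr$tip.label)) {
    stop("newick parse error: duplicate labels: ",
      paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (ape::Ntip(tr) < 2L) stop("newick parse error: fewer than 2 leaves")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0, na.rm = TRUE)) {
    stop("newick parse error: negative branch length")
  }

  sup <- rep(NA_real_, tr$Nnode)
  if (!is.null(tr$node.label)) {
    v <- suppressWarnings(as.numeric(tr$node.label))
    ok <- !is.na(v) & v >= 0 & v <= 100
    sup[ok] <- v[ok]
  }
  tr$support <- sup
  tr
}

# phylo -> recursive node list (children, label, len, support)
as_node_list <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  kids <- vector("list", n_nodes)
  elen <- rep(NA_real_, n_nodes)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]; c <- tree$edge[r, 2]
    kids[[p]] <- c(kids[[p]], c)
    if (!is.null(tree$edge.length)) elen[c] <- tree$edge.length[r]
  }
  sup <- tree_support(tree)
  build <- function(i) {
    if (i <= ntip) {
      list(label = tree$tip.label[i], len = elen[i], support = NA_real_,
           children = NULL)
    } else {
      list(label = NULL, len = elen[i], support = sup[i - ntip],
           children = lapply(kids[[i]], build))
    }
  }
  build(ntip + 1L)
}

# Inverse of as_node_list: build a phylo object directly (no Newick round
# trip), children ordered by smallest descendant label for determinism.
node_list_to_phylo <- function(root) {
  count_tips <- function(nd) {
    if (is.null(nd$children)) 1L else sum(vapply(nd$children, count_tips, 1L))
  }
  ntip <- count_tips(root)
  env <- new.env(parent = emptyenv())
  env$tip <- character(ntip)
  env$next_tip <- 0L
  env$next_int <- ntip
  env$parent <- integer(0); env$child <- integer(0); env$len <- numeric(0)
  env$sup <- numeric(0)
  min_desc <- function(nd) {
    if (is.null(nd$children)) nd$label else min(vapply(nd$children, min_desc, ""))
  }
  assign_ids <- function(nd) {
    if (is.null(nd$children)) {
      env$next_tip <- env$next_tip + 1L
      env$tip[env$next_tip] <- nd$label
      return(env$next_tip)
    }
    env$next_int <- env$next_int + 1L
    id <- env$next_int
    env$sup[id - ntip] <- nd$support %||% NA_real_
    kids <- nd$children[order(vapply(nd$children, min_desc, ""))]
    for (k in kids) {
      kid <- assign_ids(k)
      env$parent <- c(env$parent, id)
      env$child <- c(env$child, kid)
      env$len <- c(env$len, if (is.null(k$len)) NA_real_ else k$len)
    }
    id
  }
  assign_ids(root)
  nnode <- env$next_int - ntip
  phy <- structure(list(edge = cbind(env$parent, env$child),
                        tip.label = env$tip, Nnode = nnode), class = "phylo")
  if (!all(is.na(env$len))) phy$edge.length <- env$len
  phy <- stats::reorder(phy, "cladewise")
  phy$support <- env$sup[seq_len(nnode)]
  phy
}

fmt_num <- function(x) {
  format(signif(x, 6), trim = TRUE, scientific = FALSE)
}

# Deterministic serializer: children ordered by smallest descendant label.
serialize_node <- function(nd, with_lengths = TRUE) {
  if (is.null(nd$children)) {
    s <- nd$label
    mn <- nd$label
  } else {
    parts <- lapply(nd$children, serialize_node, with_lengths = with_lengths)
    mins <- vapply(parts, `[[`, "", "min")
    ord <- order(mins)
    s <- paste0("(", paste(vapply(parts[ord], `[[`, "", "str"), collapse = ","), ")")
    if (!is.na(nd$support)) s <- paste0(s, fmt_num(nd$support))
    mn <- min(mins)
  }
  if (with_lengths && !is.na(nd$len)) s <- paste0(s, ":", fmt_num(nd$len))
  list(str = s, min = mn)
}

#' Write a tree as a canonical Newick string
#'
#' Children are ordered by their smallest descendant label, branch lengths
#' printed to 6 significant digits and supports as internal node labels, so
#' output is deterministic and `parse_newick(write_newick(t))` reproduces
#' the topology, lengths and supports of `t`.
#'
#' @param tree A `phylo` tree.
#' @return A single Newick string ending in `";"`.
#' @export
write_newick <- function(tree) {
  nl <- as_node_list(tree)
  nl$len <- NA_real_  # no root edge
  paste0(serialize_node(nl)$str, ";")
}

#' Read gene trees from a multi-Newick file
#'
#' One statement per line; blank lines and `#`-prefixed comment lines are
#' skipped.
#' @param path File path.
#' @param support_convention Passed to [parse_newick()].
#' @return A list of trees.
#' @export
read_gene_trees <- function(path, support_convention = "internal-node-label") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_newick, support_convention = support_convention)
}

#' Write gene trees to a multi-Newick file
#' @param trees List of trees.
#' @param path File path.
#' @export
write_gene_trees <- function(trees, path) {
  writeLines(vapply(trees, write_newick, ""), path)
}

# Per-edge clade table: for each edge, the bitmask of tips below its child
# node (over the tree's sorted taxa), plus support and length.
clade_table <- function(tree) {
  taxa <- tree_taxa(tree)
  n <- length(taxa)
  if (n > .MAX_TAXA) stop("at most ", .MAX_TAXA, " taxa supported")
  ntip <- ape::Ntip(tree)
  tr <- stats::reorder(tree, "postorder")
  mask <- integer(ntip + tr$Nnode)
  tipbit <- bitwShiftL(1L, match(tr$tip.label, taxa) - 1L)
  mask[seq_len(ntip)] <- tipbit
  for (r in seq_len(nrow(tr$edge))) {
    p <- tr$edge[r, 1]; c <- tr$edge[r, 2]
    mask[p] <- bitwOr(mask[p], mask[c])
  }
  sup <- tree_support(tr)
  child <- tr$edge[, 2]
  list(
    child = child,
    mask = mask[child],
    support = ifelse(child > ntip, sup[pmax(child - ntip, 1L)], NA_real_),
    length = if (is.null(tr$edge.length)) rep(NA_real_, length(child)) else tr$edge.length,
    internal = child > ntip
  )
}

# Canonical non-trivial splits of the unrooted topology, with supports.
# For a rooted binary tree the two root edges induce one split; duplicates
# are merged (max support, summed length).
split_table <- function(tree) {
  taxa <- tree_taxa(tree)
  n <- length(taxa)
  ct <- clade_table(tree)
  int <- ct$internal
  if (!any(int) || n < 4L) {
    return(list(mask = integer(0), support = numeric(0), length = numeric(0)))
  }
  cmask <- canonical_split(ct$mask[int], n)
  sz <- popcount(cmask)
  keep <- sz >= 2L & sz <= n - 2L
  cmask <- cmask[keep]; sup <- ct$support[int][keep]; len <- ct$length[int][keep]
  if (anyDuplicated(cmask)) {
    # a rooted tree's two root edges induce the same split: merge, keeping
    # the maximum support and the summed length
    u <- unique(cmask)
    idx <- match(cmask, u)
    sup2 <- rep(NA_real_, length(u))
    len2 <- rep(NA_real_, length(u))
    for (k in seq_along(cmask)) {
      j <- idx[k]
      if (!is.na(sup[k])) {
        sup2[j] <- if (is.na(sup2[j])) sup[k] else max(sup2[j], sup[k])
      }
      if (!is.na(len[k])) {
        len2[j] <- if (is.na(len2[j])) len[k] else len2[j] + len[k]
      }
    }
    list(mask = u, support = sup2, length = len2)
  } else {
    list(mask = cmask, support = sup, length = len)
  }
}

#' Non-trivial bipartitions induced by a tree's internal edges
#'
#' The tree is treated as unrooted; each bipartition is reported in
#' canonical orientation (block with the lexicographically smallest taxon
#' first). With `min_support`, edges whose support is missing or below the
#' cutoff are skipped.
#'
#' @param tree A `phylo` tree with >= 4 leaves (fewer gives an empty set).
#' @param min_support Optional support cutoff in \[0, 100\].
#' @return A data frame with columns `split`, `mask`, `support`, `length`
#'   and attribute `taxa`.
#' @export
bipartition_set <- function(tree, min_support = NULL) {
  taxa <- tree_taxa(tree)
  st <- split_table(tree)
  keep <- if (is.null(min_support)) {
    rep(TRUE, length(st$mask))
  } else {
    !is.na(st$support) & st$support >= min_support
  }
  out <- data.frame(
    split = vapply(st$mask[keep], split_string, "", taxa = taxa),
    mask = st$mask[keep], support = st$support[keep], length = st$length[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "taxa") <- taxa
  class(out) <- c("bipartition_set", class(out))
  out
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the two unrooted non-trivial
#' bipartition sets; branch lengths and rooting are ignored.
#'
#' @param t1,t2 Trees on identical taxon sets.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  a <- tree_taxa(t1); b <- tree_taxa(t2)
  if (!identical(a, b)) {
    stop("unequal taxon sets; only in first: ",
      paste(setdiff(a, b), collapse = ", "), "; only in second: ",
      paste(setdiff(b, a), collapse = ", "))
  }
  s1 <- split_table(t1)$mask
  s2 <- split_table(t2)$mask
  length(s1) + length(s2) - 2L * length(intersect(s1, s2))
}

prune_node <- function(nd, keep) {
  if (is.null(nd$children)) {
    if (nd$label %in% keep) nd else NULL
  } else {
    kids <- Filter(Negate(is.null), lapply(nd$children, prune_node, keep = keep))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) {
      k <- kids[[1]]
      # suppress degree-2 node: sum lengths, keep minimum support
      if (!is.na(nd$len)) k$len <- if (is.na(k$len)) nd$len else k$len + nd$len
      s <- c(k$support, nd$support)
      k$support <- if (all(is.na(s))) NA_real_ else min(s, na.rm = TRUE)
      return(k)
    }
    nd$children <- kids
    nd
  }
}

#' Restrict a tree to a taxon subset
#'
#' Prunes all other leaves, suppresses resulting degree-2 nodes (summing
#' branch lengths and keeping the minimum support across merged edges).
#'
#' @param tree A `phylo` tree.
#' @param taxa Subset of the tree's taxa, at least 2.
#' @return The restricted tree.
#' @export
restrict_to_taxa <- function(tree, taxa) {
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0L) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) < 2L) stop("need at least 2 taxa")
  if (setequal(taxa, tree$tip.label)) return(tree)
  nd <- prune_node(as_node_list(tree), keep = taxa)
  nd$len <- NA_real_
  nd$support <- NA_real_
  node_list_to_phylo(nd)
}

# Fast induced-quartet resolution from canonical split masks.
# quartet_masks: integer vector of 4-bit masks; returns the mask of the pair
# containing the lowest-set bit of each quartet, or 0L when unresolved.
quartet_pair_masks <- function(split_masks, quartet_masks) {
  res <- integer(length(quartet_masks))
  if (length(split_masks) == 0L) return(res)
  low <- bitwAnd(quartet_masks, bitwNot(quartet_masks - 1L) )  # lowest set bit
  todo <- rep(TRUE, length(quartet_masks))
  for (s in split_masks) {
    if (!any(todo)) break
    x <- bitwAnd(s, quartet_masks[todo])
    hit <- popcount(x) == 2L
    if (any(hit)) {
      idx <- which(todo)[hit]
      xm <- x[hit]
      flip <- bitwAnd(xm, low[idx]) == 0L
      xm[flip] <- bitwXor(quartet_masks[idx[flip]], xm[flip])
      res[idx] <- xm
      todo[idx] <- FALSE
    }
  }
  res
}

# Rooted-triple resolution from clade masks: mask of the cherry pair, or 0L.
triple_pair_masks <- function(clade_masks, triple_masks) {
  res <- integer(length(triple_masks))
  if (length(clade_masks) == 0L) return(res)
  todo <- rep(TRUE, length(triple_masks))
  for (s in clade_masks) {
    if (!any(todo)) break
    x <- bitwAnd(s, triple_masks[todo])
    hit <- popcount(x) == 2L
    if (any(hit)) {
      idx <- which(todo)[hit]
      res[idx] <- x[hit]
      todo[idx] <- FALSE
    }
  }
  res
}

#' Induced subtree topology for a quartet or rooted triple
#'
#' For four taxa (unrooted) returns which pair is split from the other two,
#' e.g. `"A,B|C,D"`; for three taxa with `rooted = TRUE` returns the pair
#' that coalesces first, e.g. `"A,B"`. Polytomies give `"unresolved"`.
#'
#' @param tree A `phylo` tree.
#' @param taxa Exactly 3 (rooted) or 4 (unrooted) taxon labels.
#' @param rooted Interpret as a rooted triple.
#' @return A character scalar.
#' @export
induced_topology <- function(tree, taxa, rooted = FALSE) {
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0L) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  all_taxa <- tree_taxa(tree)
  m <- taxa_to_mask(taxa, all_taxa)
  if (rooted) {
    if (length(taxa) != 3L) stop("rooted mode expects exactly 3 taxa")
    if (!ape::is.rooted(tree)) stop("rooted mode requires a rooted tree")
    ct <- clade_table(tree)
    pm <- triple_pair_masks(ct$mask[ct$internal], m)
    if (pm == 0L) return("unresolved")
    paste(mask_to_taxa(pm, all_taxa), collapse = ",")
  } else {
    if (length(taxa) != 4L) stop("quartet mode expects exactly 4 taxa")
    pm <- quartet_pair_masks(split_table(tree)$mask, m)
    if (pm == 0L) return("unresolved")
    b1 <- mask_to_taxa(pm, all_taxa)
    b2 <- mask_to_taxa(bitwXor(m, pm), all_taxa)
    if (min(b2) < min(b1)) { tmp <- b1; b1 <- b2; b2 <- tmp }
    paste(paste(b1, collapse = ","), paste(b2, collapse = ","), sep = "|")
  }
}

# Build a tree from a laminar family of canonical split masks (none contain
# taxon 1); supports attached as internal node labels.
tree_from_splits <- function(masks, supports, taxa) {
  n <- length(taxa)
  fm <- full_mask(n)
  ord <- order(popcount(masks), decreasing = TRUE)
  masks <- masks[ord]; supports <- supports[ord]
  make <- function(members, cand_idx) {
    # cand_idx: indices of masks strictly inside `members`
    taken <- 0L
    parts <- character(0)
    i <- 1
    while (i <= length(cand_idx)) {
      j <- cand_idx[i]
      if (bitwAnd(masks[j], taken) == 0L) {
        inside <- cand_idx[cand_idx > j & bitwAnd(masks[cand_idx], bitwNot(masks[j])) == 0L &
                             masks[cand_idx] != masks[j]]
        sub <- make(masks[j], inside)
        parts <- c(parts, paste0(sub, if (!is.na(supports[j])) fmt_num(supports[j]) else ""))
        taken <- bitwOr(taken, masks[j])
      }
      i <- i + 1
    }
    loose <- mask_to_taxa(bitwAnd(members, bitwNot(taken)), taxa)
    parts <- c(parts, loose)
    ord2 <- order(vapply(parts, function(p) {
      toks <- regmatches(p, gregexpr("[^(),:;|]+", p))[[1]]
      min(toks[toks %in% taxa])
    }, ""))
    paste0("(", paste(parts[ord2], collapse = ","), ")")
  }
  rest <- bitwAnd(fm, bitwNot(1L))
  inner <- make(rest, seq_along(masks))
  parse_newick(paste0("(", taxa[1], ",", substring(inner, 2L), ";"))
}

#' Majority-rule consensus of a collection of trees
#'
#' Retains exactly the bipartitions whose frequency strictly exceeds
#' `threshold`; each retained edge is annotated with its frequency times 100
#' as support.
#'
#' @param trees Non-empty list of trees on a shared taxon set.
#' @param threshold Fraction in \[0.5, 1\].
#' @return The consensus tree.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(length(trees) >= 1L, threshold >= 0.5, threshold <= 1)
  taxa <- tree_taxa(trees[[1]])
  for (t in trees) {
    if (!identical(tree_taxa(t), taxa)) stop("mixed taxon sets in consensus input")
  }
  all_masks <- unlist(lapply(trees, function(t) unique(split_table(t)$mask)))
  if (length(all_masks) == 0L) {
    return(parse_newick(paste0("(", paste(taxa, collapse = ","), ");")))
  }
  tab <- table(all_masks)
  freq <- as.numeric(tab) / length(trees)
  keep <- freq > threshold
  masks <- as.integer(names(tab))[keep]
  tree_from_splits(masks, freq[keep] * 100, taxa)
}

#' Reroot a tree on an outgroup taxon
#'
#' Returns a rooted tree whose root separates the outgroup leaf from all
#' other taxa; the unrooted bipartition set (and supports, which travel with
#' their edges) is unchanged.
#'
#' @param tree A `phylo` tree.
#' @param outgroup A leaf label.
#' @return A rooted tree.
#' @export
reroot <- function(tree, outgroup) {
  if (!(outgroup %in% tree$tip.label)) stop("unknown outgroup: ", outgroup)
  phy <- tree
  sup <- tree_support(phy)
  phy$node.label <- ifelse(is.na(sup), "", fmt_num(sup))
  og_idx <- which(phy$tip.label == outgroup)
  already <- FALSE
  if (ape::is.rooted(phy)) {
    ct <- clade_table(phy)
    root_children <- ct$mask[ct$child %in% phy$edge[phy$edge[, 1] == ape::Ntip(phy) + 1L, 2]]
    ogbit <- bitwShiftL(1L, match(outgroup, tree_taxa(phy)) - 1L)
    already <- any(root_children == ogbit)
  }
  if (!already) {
    phy <- ape::unroot(phy)
    phy <- ape::root(phy, outgroup = og_idx <- which(phy$tip.label == outgroup),
                     resolve.root = TRUE, edgelabel = TRUE)
  }
  v <- suppressWarnings(as.numeric(phy$node.label))
  phy$support <- ifelse(!is.na(v) & v >= 0 & v <= 100, v, NA_real_)
  phy$node.label <- NULL
  phy
}
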