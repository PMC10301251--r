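# Internal helpers: bitmask split algebra and seeded evaluation.
#
# Taxon sets are encoded as 32-bit integer masks over the lexicographically
# sorted taxon labels of a tree (bit i-1 set <=> taxon i present). This caps
# trees at 30 taxa, comfortably above the 9-26 taxa this package targets.

.MAX_TAXA <- 30L

# 16-bit popcount lookup, built once at load.
.pkg_env <- new.env(parent = emptyenv())

.popcount_table <- function() {
  if (is.null(.pkg_env$poptab)) {
    b <- 0:65535
    cnt <- integer(65536L)
    while (any(b > 0L)) {
      cnt <- cnt + (b %% 2L)
      b <- b %/% 2L
    }
    .pkg_env$poptab <- cnt
  }
  .pkg_env$poptab
}

popcount <- function(x) {
  tab <- .popcount_table()
  tab[bitwAnd(x, 65535L) + 1L] + tab[bitwShiftR(x, 16L) + 1L]
}

full_mask <- function(n) {
  stopifnot(n <= .MAX_TAXA)
  if (n == 31L) stop("at most 30 taxa supported")
  bitwShiftL(1L, n) - 1L
}

# Canonical split orientation: the block NOT containing the first (smallest)
# taxon. Input and output are masks over the sorted taxon vector.
canonical_split <- function(mask, n) {
  fm <- full_mask(n)
  flip <- bitwAnd(mask, 1L) == 1L
  out <- mask
  out[flip] <- bitwXor(fm, mask[flip])
  out
}

mask_to_taxa <- function(mask, taxa) {
  taxa[bitwAnd(bitwShiftR(mask, seq_along(taxa) - 1L), 1L) == 1L]
}

taxa_to_mask <- function(labels, taxa) {
  idx <- match(labels, taxa)
  if (anyNA(idx)) stop("unknown taxa: ", paste(labels[is.na(idx)], collapse = ", "))
  out <- 0L
  for (i in idx) out <- bitwOr(out, bitwShiftL(1L, i - 1L))
  out
}

split_string <- function(mask, taxa) {
  n <- length(taxa)
  m <- canonical_split(mask, n)
  b1 <- mask_to_taxa(bitwXor(full_mask(n), m), taxa)
  b2 <- mask_to_taxa(m, taxa)
  paste(paste(b1, collapse = ","), paste(b2, collapse = ","), sep = "|")
}

# Run code with a local, restored RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stage sub-seed from a master seed; stays below 2^31.
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(master) * 48271 + h * 16807) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
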