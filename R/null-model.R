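# Shared constrained-randomization kernel (Raup-Crick lineage).
#
# A null realization of a sample preserves its observed richness S and read
# depth N. OTU identities are drawn without replacement with probability
# proportional to occupancy frequency across the dataset; each drawn OTU
# receives one read and the remaining N - S reads are distributed
# multinomially in proportion to the metacommunity mean relative abundance
# of the drawn OTUs. This single kernel backs the Hill null, the beta-null
# deviation and RC_bray so the three stages share one null hypothesis.

# Precompute kernel parameters from a count table.
.null_kernel <- function(table) {
  occ <- colMeans(table > 0)
  rel <- to_relative(table)
  meta <- colMeans(rel)
  keep <- occ > 0
  list(otu_ids = colnames(table)[keep], occ = occ[keep], meta = meta[keep],
       n_otus = sum(keep))
}

# One null count vector with richness s and depth n (uses the session RNG).
.null_sample <- function(kernel, s, n) {
  if (s > kernel$n_otus)
    stop("sample richness exceeds the number of occupied OTUs in the table")
  idx <- sample.int(kernel$n_otus, s, replace = FALSE, prob = kernel$occ)
  counts <- rep(1L, s)
  extra <- n - s
  if (extra > 0) {
    w <- kernel$meta[idx]
    if (sum(w) <= 0) w <- rep(1, s)
    counts <- counts + as.integer(stats::rmultinom(1, extra, w))
  }
  out <- numeric(kernel$n_otus)
  out[idx] <- counts
  names(out) <- kernel$otu_ids
  out
}

# Matrix of n_iter null realizations of a sample (rows = iterations).
.null_samples <- function(kernel, s, n, n_iter) {
  t(vapply(seq_len(n_iter), function(i) .null_sample(kernel, s, n),
           numeric(kernel$n_otus)))
}

# Null realizations as relative abundances aligned to a tip ordering.
# ord: for each tip, its index into kernel$otu_ids (NA if absent).
.null_rel_tips <- function(kernel, s, n, n_iter, ord) {
  M <- .null_samples(kernel, s, n, n_iter)
  M <- M / rowSums(M)
  out <- matrix(0, n_iter, length(ord))
  ok <- !is.na(ord)
  out[, ok] <- M[, ord[ok], drop = FALSE]
  out
}
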