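# Independent oracles and fixture builders. Each oracle is a deliberately
# naive implementation (explicit loops, no shared code with the package)
# used to freeze expected values.

# weighted normalized UniFrac via per-edge descendant sets obtained from
# phangorn (independent of the package's postorder accumulation)
naive_weighted_unifrac <- function(p1, p2, tree) {
  p1 <- p1[tree$tip.label]; p2 <- p2[tree$tip.label]
  p1[is.na(p1)] <- 0; p2[is.na(p2)] <- 0
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- unlist(phangorn::Descendants(tree, child, type = "tips"))
    a <- sum(p1[tips]); b <- sum(p2[tips])
    num <- num + tree$edge.length[e] * abs(a - b)
    den <- den + tree$edge.length[e] * (a + b)
  }
  if (den == 0) 0 else num / den
}

# abundance-weighted beta-mean-nearest-taxon distance by double loop
naive_bmntd <- function(p1, p2, D) {
  s1 <- names(p1)[p1 > 0]; s2 <- names(p2)[p2 > 0]
  w1 <- p1[s1] / sum(p1[s1]); w2 <- p2[s2] / sum(p2[s2])
  d12 <- 0
  for (i in s1) d12 <- d12 + w1[i] * min(D[i, s2])
  d21 <- 0
  for (j in s2) d21 <- d21 + w2[j] * min(D[s1, j])
  unname(0.5 * (d12 + d21))
}

# exhaustive tip-permutation null for bNTI on tiny trees
naive_bnti_exhaustive <- function(p1, p2, tree) {
  D <- ape::cophenetic.phylo(tree)
  n <- nrow(D)
  perms <- rbind(1)
  for (k in 2:n) {
    out <- NULL
    for (i in seq_len(k))
      out <- rbind(out, cbind(i, perms + (perms >= i)))
    perms <- out
  }
  obs <- naive_bmntd(p1, p2, D)
  nulls <- apply(perms, 1, function(pm) {
    Dp <- D[pm, pm]
    dimnames(Dp) <- dimnames(D)
    naive_bmntd(p1, p2, Dp)
  })
  (obs - mean(nulls)) / stats::sd(nulls)
}

naive_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# random count table fixture
random_table <- function(n_samples, n_otus, seed = 1, lambda = 8,
                         sparsity = 0.4) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_otus, lambda) *
                (stats::runif(n_samples * n_otus) > sparsity),
              n_samples, n_otus)
  m[rowSums(m) == 0, 1] <- 1
  dimnames(m) <- list(paste0("S", seq_len(n_samples)),
                      paste0("OTU_", seq_len(n_otus)))
  storage.mode(m) <- "integer"
  m
}

# a table drawn from the package's constrained-randomization kernel itself,
# so the null hypothesis holds by construction
null_generated_table <- function(base_table, seed = 1) {
  set.seed(seed)
  kernel <- assemblage:::.null_kernel(base_table)
  S <- rowSums(base_table > 0); N <- rowSums(base_table)
  out <- t(vapply(seq_len(nrow(base_table)), function(i)
    assemblage:::.null_sample(kernel, S[i], N[i]), numeric(kernel$n_otus)))
  rownames(out) <- rownames(base_table)
  storage.mode(out) <- "integer"
  out
}
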