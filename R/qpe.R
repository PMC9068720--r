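# Quantitative process estimates: abundance-weighted beta-mean-nearest-taxon
# distance (bMNTD), its standardized deviation from a tip-shuffle null
# (bNTI), abundance-weighted Raup-Crick on Bray-Curtis (RC_bray), and the
# five-way assembly-process classification:
#   bNTI >  2                      -> variable selection
#   bNTI < -2                      -> homogeneous selection
#   else RC_bray >  0.95           -> dispersal limitation
#        RC_bray < -0.95           -> homogenizing dispersal
#        otherwise                 -> undominated

PROCESS_LEVELS <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated")

# Core bMNTD on weight vectors indexed over the tips of a patristic matrix.
# map optionally re-addresses tip i to row/column map[i] of D (tip shuffle).
.bmntd <- function(w1, w2, D, map = NULL) {
  s1 <- which(w1 > 0); s2 <- which(w2 > 0)
  if (length(s1) == 0 || length(s2) == 0)
    stop("beta_mntd: a community has zero taxa")
  i1 <- if (is.null(map)) s1 else map[s1]
  i2 <- if (is.null(map)) s2 else map[s2]
  Ds <- D[i1, i2, drop = FALSE]
  rmin <- Ds[cbind(seq_along(i1), max.col(-Ds, ties.method = "first"))]
  cmin <- Ds[cbind(max.col(-t(Ds), ties.method = "first"), seq_along(i2))]
  0.5 * (sum(w1[s1] / sum(w1[s1]) * rmin) +
           sum(w2[s2] / sum(w2[s2]) * cmin))
}

#' Abundance-weighted beta-mean-nearest-taxon distance
#'
#' For each taxon present in one community, the patristic distance to its
#' closest relative present in the other community, weighted by relative
#' abundance; the two directions are averaged. Shared taxa contribute zero
#' distance, so identical communities give 0.
#'
#' @param p1,p2 relative-abundance vectors named by OTU (or ordered as the
#'   tree tips).
#' @param tree rooted `phylo` with branch lengths.
#' @return non-negative real in tree branch-length units.
#' @export
beta_mntd <- function(p1, p2, tree) {
  D <- ape::cophenetic.phylo(tree)
  w1 <- .align_to_tips(p1, rownames(D))
  w2 <- .align_to_tips(p2, rownames(D))
  .bmntd(w1, w2, D)
}

# All permutations of 1..n (rows); used for the exhaustive bNTI null.
.permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, p + (p >= i))))
}

#' Beta-nearest-taxon index
#'
#' Standardized deviation of the observed bMNTD from a null distribution
#' generated by shuffling taxon positions across the phylogeny (tip-label
#' shuffle over the whole tree):
#' `(observed - mean(null)) / sd(null)`.
#'
#' @param p1,p2 relative-abundance vectors named by OTU.
#' @param tree rooted `phylo`.
#' @param n_iter number of sampled shuffles (ignored for `null = "exhaustive"`).
#' @param seed optional integer seed.
#' @param null `"sample"` (default) or `"exhaustive"` (all tip permutations;
#'   only sensible for very small trees).
#' @return the bNTI z-score; `NA` with a warning when the null SD is 0
#'   (degenerate phylogeny, e.g. a star tree).
#' @export
beta_nti <- function(p1, p2, tree, n_iter = 999, seed = NULL,
                     null = c("sample", "exhaustive")) {
  null <- match.arg(null)
  D <- ape::cophenetic.phylo(tree)
  n <- nrow(D)
  w1 <- .align_to_tips(p1, rownames(D))
  w2 <- .align_to_tips(p2, rownames(D))
  obs <- .bmntd(w1, w2, D)
  if (null == "exhaustive") {
    if (n > 8) stop("exhaustive null is limited to trees with <= 8 tips")
    perms <- .permutations(n)
    nulls <- apply(perms, 1, function(pm) .bmntd(w1, w2, D, map = pm))
  } else {
    if (n_iter < 2) stop("n_iter must be >= 2")
    if (!is.null(seed)) set.seed(seed)
    nulls <- vapply(seq_len(n_iter),
                    function(i) .bmntd(w1, w2, D, map = sample.int(n)),
                    numeric(1))
  }
  s <- stats::sd(nulls)
  if (!is.finite(s) || s == 0) {
    warning("null SD of bMNTD is zero (degenerate phylogeny); bNTI undefined")
    return(NA_real_)
  }
  (obs - mean(nulls)) / s
}

# Bray-Curtis between two count vectors.
.bray <- function(x, y) {
  tot <- sum(x) + sum(y)
  if (tot == 0) return(1)
  sum(abs(x - y)) / tot
}

# RC_bray core given a kernel and the two samples' (richness, depth).
.rc_bray <- function(kernel, s1, n1, s2, n2, obs_bc, n_iter) {
  nulls <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    a <- .null_sample(kernel, s1, n1)
    b <- .null_sample(kernel, s2, n2)
    nulls[it] <- .bray(a, b)
  }
  2 * ((sum(nulls < obs_bc) + 0.5 * sum(nulls == obs_bc)) / n_iter) - 1
}

#' Abundance-weighted Raup-Crick metric (RC_bray)
#'
#' Compares the observed Bray-Curtis dissimilarity of a sample pair with a
#' null distribution of pairs assembled by the shared constrained-
#' randomization kernel (observed richness by occupancy-weighted draws,
#' observed depth distributed by metacommunity relative abundance). Scaled
#' to `[-1, 1]`:
#' `RC = 2 [ #(null < obs) + 0.5 #(null = obs) ] / n_iter - 1`.
#'
#' @param s1,s2 sample names in `table`, or count vectors named by the
#'   table's OTUs.
#' @param table samples x OTUs count matrix supplying the metacommunity
#'   context.
#' @param n_iter null iterations (default 999).
#' @param seed optional integer seed.
#' @return RC_bray in `[-1, 1]`.
#' @export
raup_crick_bray <- function(s1, s2, table, n_iter = 999, seed = NULL) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  table <- validate_count_table(table)
  pick <- function(s) {
    if (is.character(s) && length(s) == 1) {
      if (!(s %in% rownames(table))) stop("sample not in table: ", s)
      table[s, ]
    } else {
      v <- numeric(ncol(table)); names(v) <- colnames(table)
      common <- intersect(names(s), names(v))
      v[common] <- s[common]
      v
    }
  }
  x <- pick(s1); y <- pick(s2)
  if (!is.null(seed)) set.seed(seed)
  kernel <- .null_kernel(table)
  .rc_bray(kernel, sum(x > 0), sum(x), sum(y > 0), sum(y),
           .bray(x, y), n_iter)
}

#' Classify a sample pair into one of five assembly processes
#'
#' Implements the standard decision tree: `bNTI > 2` variable selection,
#' `bNTI < -2` homogeneous selection, otherwise `RC_bray > 0.95` dispersal
#' limitation, `RC_bray < -0.95` homogenizing dispersal, else undominated.
#'
#' @param beta_nti finite bNTI value.
#' @param rc_bray RC_bray value; may be `NA` only when `|beta_nti| > 2`.
#' @return one of `"variable_selection"`, `"homogeneous_selection"`,
#'   `"dispersal_limitation"`, `"homogenizing_dispersal"`, `"undominated"`.
#' @export
classify_pair <- function(beta_nti, rc_bray = NA_real_) {
  if (!is.finite(beta_nti)) stop("beta_nti must be finite")
  if (beta_nti > 2) return("variable_selection")
  if (beta_nti < -2) return("homogeneous_selection")
  if (is.na(rc_bray)) stop("rc_bray required when |beta_nti| <= 2")
  if (rc_bray > 0.95) return("dispersal_limitation")
  if (rc_bray < -0.95) return("homogenizing_dispersal")
  "undominated"
}

#' Percentage contribution of assembly processes per group
#'
#' @param processes character vector of process labels (see
#'   [classify_pair()]).
#' @param groups grouping label per pair.
#' @return data.frame with one row per group, the five process percentages
#'   (summing to 100) and the pair count.
#' @export
process_percentages <- function(processes, groups) {
  if (length(processes) == 0) stop("no classified pairs")
  if (length(groups) != length(processes))
    stop("groups must have one entry per pair")
  bad <- setdiff(unique(processes), PROCESS_LEVELS)
  if (length(bad) > 0) stop("unknown process label(s): ", paste(bad, collapse = ", "))
  out <- do.call(rbind, lapply(split(processes, groups), function(p) {
    tab <- table(factor(p, levels = PROCESS_LEVELS))
    as.data.frame(c(as.list(100 * tab / length(p)), n_pairs = length(p)))
  }))
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Quantitative process estimates for a community table
#'
#' Runs the full QPE workflow: bMNTD and bNTI for every sample pair (null
#' tip shuffles are shared across pairs within an iteration), RC_bray for
#' pairs not already assigned to selection, the five-way classification,
#' and per-group percentage summaries.
#'
#' @param table samples x OTUs count matrix.
#' @param tree rooted `phylo` covering the table's OTUs.
#' @param groups group label per sample (or named by sample id).
#' @param n_iter null iterations for bNTI (default 999).
#' @param rc_n_iter null iterations for RC_bray (default `n_iter`).
#' @param pairs `"within"` (default) classifies within-group pairs and
#'   summarizes per group; `"between"` classifies cross-group pairs and
#'   summarizes per group pair.
#' @param seed optional integer seed.
#' @return object of class `qpe` with `pairs` (per-pair statistics and
#'   labels) and `summary` (per-group process percentages).
#' @export
qpe <- function(table, tree, groups, n_iter = 999, rc_n_iter = n_iter,
                pairs = c("within", "between"), seed = NULL) {
  pairs <- match.arg(pairs)
  if (n_iter < 2) stop("n_iter must be >= 2")
  bundle <- align_inputs(table, tree)
  table <- bundle$table; tree <- bundle$tree
  groups <- .match_groups(groups, table)
  if (!is.null(seed)) set.seed(seed)
  D <- ape::cophenetic.phylo(tree)
  rel <- to_relative(table)[, rownames(D), drop = FALSE]
  n <- ncol(rel)
  ns <- nrow(rel)
  idx <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  same <- groups[idx[, 1]] == groups[idx[, 2]]
  keep <- if (pairs == "within") same else !same
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0) stop("no ", pairs, "-group sample pairs to classify")
  pair_group <- if (pairs == "within") groups[idx[, 1]] else
    paste(pmin(groups[idx[, 1]], groups[idx[, 2]]),
          pmax(groups[idx[, 1]], groups[idx[, 2]]), sep = ":")
  obs <- vapply(seq_len(nrow(idx)), function(k)
    .bmntd(rel[idx[k, 1], ], rel[idx[k, 2], ], D), numeric(1))
  nulls <- matrix(NA_real_, nrow(idx), n_iter)
  for (it in seq_len(n_iter)) {
    pm <- sample.int(n)
    nulls[, it] <- vapply(seq_len(nrow(idx)), function(k)
      .bmntd(rel[idx[k, 1], ], rel[idx[k, 2], ], D, map = pm), numeric(1))
  }
  nm <- rowMeans(nulls)
  nsd <- apply(nulls, 1, stats::sd)
  bnti <- ifelse(nsd > 0, (obs - nm) / nsd, NA_real_)
  if (anyNA(bnti))
    warning(sum(is.na(bnti)), " pair(s) with zero null SD; bNTI undefined")
  kernel <- .null_kernel(table)
  S <- rowSums(table > 0); N <- rowSums(table)
  rc <- rep(NA_real_, nrow(idx))
  need_rc <- which(!is.na(bnti) & abs(bnti) <= 2)
  for (k in need_rc) {
    a <- idx[k, 1]; b <- idx[k, 2]
    rc[k] <- .rc_bray(kernel, S[a], N[a], S[b], N[b],
                      .bray(table[a, ], table[b, ]), rc_n_iter)
  }
  proc <- rep(NA_character_, nrow(idx))
  ok <- !is.na(bnti)
  proc[ok] <- mapply(classify_pair, bnti[ok], rc[ok])
  pair_df <- data.frame(
    group = pair_group,
    sample_a = rownames(rel)[idx[, 1]],
    sample_b = rownames(rel)[idx[, 2]],
    beta_mntd = obs, beta_nti = bnti, rc_bray = rc, process = proc,
    stringsAsFactors = FALSE)
  summ <- process_percentages(proc[!is.na(proc)], pair_group[!is.na(proc)])
  structure(list(pairs = pair_df, summary = summ,
                 n_iter = n_iter, rc_n_iter = rc_n_iter, mode = pairs),
            class = "qpe")
}

#' @export
print.qpe <- function(x, ...) {
  cat("Quantitative process estimates (", nrow(x$pairs), " ", x$mode,
      "-group pairs, ", x$n_iter, " bNTI nulls, ", x$rc_n_iter,
      " RC nulls)\n", sep = "")
  cat("Process percentages per group:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.qpe <- function(object, ...) object$summary
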