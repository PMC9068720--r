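# Branch-wise phylogenetic machinery: per-edge descendant abundances,
# Generalized UniFrac, and Faith's PD. All operations work on an ape
# "phylo" tree whose tips carry the OTU identifiers.

# Postorder edge list; each edge is (parent, child); child of the e-th edge
# subtends the e-th branch.
.postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, length = tr$edge.length,
       ntip = length(tr$tip.label), tip.label = tr$tip.label)
}

# Per-edge total abundance for one or more communities.
# P: communities x tips matrix, columns ordered as tree$tip.label.
# Returns communities x edges matrix (edges in postorder).
.edge_abundances <- function(po, P) {
  n <- nrow(P)
  A <- matrix(0, n, max(po$edge))
  A[, seq_len(po$ntip)] <- P
  for (e in seq_len(nrow(po$edge))) {
    A[, po$edge[e, 1]] <- A[, po$edge[e, 1]] + A[, po$edge[e, 2]]
  }
  A[, po$edge[, 2], drop = FALSE]
}

# Align a named abundance vector to the tree tip order (absent tips -> 0).
.align_to_tips <- function(p, tip_labels) {
  if (is.null(names(p))) {
    if (length(p) != length(tip_labels))
      stop("unnamed abundance vector must match the number of tips")
    return(as.numeric(p))
  }
  extra <- setdiff(names(p)[p > 0], tip_labels)
  if (length(extra) > 0)
    stop("taxa with positive abundance missing from tree: ",
         paste(utils::head(extra, 5), collapse = ", "))
  out <- numeric(length(tip_labels))
  names(out) <- tip_labels
  common <- intersect(names(p), tip_labels)
  out[common] <- p[common]
  as.numeric(out)
}

#' Generalized UniFrac dissimilarity between two communities
#'
#' Branch-wise weighted difference with abundance exponent `alpha`:
#' \deqn{d_\alpha = \frac{\sum_e b_e (p_{Ae}+p_{Be})^\alpha
#'   \left|\frac{p_{Ae}-p_{Be}}{p_{Ae}+p_{Be}}\right|}
#'   {\sum_e b_e (p_{Ae}+p_{Be})^\alpha}}
#' where \eqn{p_{Ae}} is the total relative abundance of tips descending
#' from branch `e` in community A. `alpha = 1` equals weighted normalized
#' UniFrac; `alpha = 0.5` (the default) is the usual compromise that
#' moderates the weight of highly abundant lineages.
#'
#' @param p1,p2 relative-abundance vectors (summing to 1), named by OTU or
#'   ordered as `tree$tip.label`.
#' @param tree rooted `phylo` with branch lengths.
#' @param alpha abundance exponent in `[0, 1]`.
#' @return dissimilarity in `[0, 1]`.
#' @export
generalized_unifrac <- function(p1, p2, tree, alpha = 0.5) {
  po <- .postorder_edges(tree)
  P <- rbind(.align_to_tips(p1, po$tip.label), .align_to_tips(p2, po$tip.label))
  .gunifrac_pair(po, P[1, ], P[2, ], alpha)
}

# Core on tip-aligned numeric vectors.
.gunifrac_pair <- function(po, a, b, alpha) {
  E <- .edge_abundances(po, rbind(a, b))
  pa <- E[1, ]; pb <- E[2, ]
  tot <- pa + pb
  keep <- tot > 0 & po$length > 0
  if (!any(keep)) return(0)
  w <- po$length[keep] * tot[keep]^alpha
  num <- sum(w * abs(pa[keep] - pb[keep]) / tot[keep])
  den <- sum(w)
  if (den == 0) return(0)
  min(max(num / den, 0), 1)
}

#' Faith's phylogenetic diversity of a taxon set
#'
#' Total branch length of the minimal subtree spanning the set and the root
#' of the tree.
#'
#' @param taxa character vector of tip labels (or logical/numeric index over
#'   tips).
#' @param tree rooted `phylo` with branch lengths.
#' @return non-negative total branch length.
#' @export
faith_pd <- function(taxa, tree) {
  if (is.character(taxa)) {
    idx <- match(taxa, tree$tip.label)
    if (anyNA(idx)) stop("taxa not in tree: ",
                         paste(taxa[is.na(idx)], collapse = ", "))
  } else {
    idx <- which(as.logical(taxa)) # logical mask over tips
    if (is.numeric(taxa) && !is.logical(taxa)) idx <- as.integer(taxa)
  }
  if (length(idx) == 0) stop("empty taxon set")
  po <- .postorder_edges(tree)
  present <- logical(max(po$edge))
  present[idx] <- TRUE
  pd <- 0
  for (e in seq_len(nrow(po$edge))) {
    if (present[po$edge[e, 2]]) {
      pd <- pd + po$length[e]
      present[po$edge[e, 1]] <- TRUE
    }
  }
  pd
}

# Edge paths from each tip to the root, as indices into the postorder edge
# list; used for incremental PD accumulation.
.tip_edge_paths <- function(po) {
  nedge <- nrow(po$edge)
  parent_edge <- integer(max(po$edge)) # edge index subtending node
  parent_edge[po$edge[, 2]] <- seq_len(nedge)
  lapply(seq_len(po$ntip), function(tip) {
    path <- integer(0)
    node <- tip
    while (parent_edge[node] != 0) {
      e <- parent_edge[node]
      path <- c(path, e)
      node <- po$edge[e, 1]
    }
    path
  })
}
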