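# Hill-order dissimilarity between pairs of communities across a grid of
# diversity orders q, with a constrained-randomization null expectation.
# q tunes the weight of abundant OTUs: q = 0 is presence/absence (Jaccard
# under the regional viewpoint), q = 1 weighs OTUs by relative abundance
# (Horn overlap at the analytic limit), q = 2 emphasizes dominant OTUs.

#' Hill-order dissimilarity between two communities
#'
#' Computes the two-assemblage Hill-number beta diversity
#' (gamma/alpha decomposition with equal assemblage weights) at diversity
#' order `q` and transforms it to a dissimilarity in `[0, 1]`. Under the
#' `"regional"` viewpoint (default) the q = 0 case equals the Jaccard
#' dissimilarity; under `"local"` it equals Sorensen. Both viewpoints
#' coincide at q = 1, where the analytic limit (log-scale beta) is used.
#'
#' @param p1,p2 relative-abundance vectors over the same OTU axis, each
#'   summing to 1.
#' @param q diversity order, a single real >= 0.
#' @param viewpoint `"regional"` (1 - U_qN family) or `"local"` (1 - C_qN).
#' @return dissimilarity in `[0, 1]`; 0 for identical communities, 1 for
#'   disjoint supports.
#' @export
hill_dissimilarity <- function(p1, p2, q, viewpoint = c("regional", "local")) {
  viewpoint <- match.arg(viewpoint)
  if (length(q) != 1 || is.na(q) || q < 0) stop("q must be a single real >= 0")
  if (length(p1) != length(p2)) stop("abundance vectors differ in length")
  if (!is.null(names(p1)) && !is.null(names(p2)) && !identical(names(p1), names(p2)))
    stop("abundance vectors have mismatched OTU axes")
  if (abs(sum(p1) - 1) > 1e-6 || abs(sum(p2) - 1) > 1e-6)
    stop("abundance vectors must each sum to 1")
  beta <- .hill_beta(p1, p2, q)
  .hill_beta_to_dissim(beta, q, viewpoint)
}

# Two-assemblage beta = gamma/alpha in [1, 2].
.hill_beta <- function(p1, p2, q) {
  if (abs(q - 1) < 1e-9) {
    g <- (p1 + p2) / 2
    hg <- -sum(g[g > 0] * log(g[g > 0]))
    w <- c(p1, p2) / 2
    ha <- -sum(w[w > 0] * log(w[w > 0]))
    alpha <- exp(ha) / 2
    gamma <- exp(hg)
  } else {
    e <- 1 / (1 - q)
    g <- (p1 + p2) / 2
    gamma <- sum(g[g > 0]^q)^e
    w <- c(p1 / 2, p2 / 2)
    alpha <- 0.5 * sum(w[w > 0]^q)^e
  }
  min(max(gamma / alpha, 1), 2)
}

.hill_beta_to_dissim <- function(beta, q, viewpoint) {
  if (abs(q - 1) < 1e-9) {
    d <- log(beta) / log(2)
  } else if (viewpoint == "regional") {
    u <- ((1 / beta)^(1 - q) - 0.5^(1 - q)) / (1 - 0.5^(1 - q))
    d <- 1 - u
  } else {
    cqn <- 1 - (beta^(1 - q) - 1) / (2^(1 - q) - 1)
    d <- 1 - cqn
  }
  min(max(d, 0), 1)
}

#' Hill dissimilarity curves with a constrained-randomization null
#'
#' For every between-group sample pair of the requested comparisons the
#' observed Hill dissimilarity is computed on a grid of diversity orders,
#' together with the mean and SD of `n_iter` null pairs. Null samples
#' preserve each observed sample's richness and read depth; OTU identities
#' are drawn with probability proportional to dataset occupancy and reads
#' are distributed in proportion to metacommunity mean relative abundance
#' (the Raup-Crick-style kernel shared with [beta_null_deviation()] and
#' [raup_crick_bray()]).
#'
#' @param table samples x OTUs count matrix.
#' @param groups character vector of group labels, one per sample of
#'   `table` (or named by sample id).
#' @param comparisons list of length-2 character vectors naming group pairs
#'   to compare; default: all unordered pairs of distinct groups.
#' @param q_grid ordered diversity orders (default 0 to 3 by 0.25).
#' @param n_iter number of null iterations (default 999).
#' @param viewpoint passed to [hill_dissimilarity()].
#' @param seed optional integer seed.
#' @return object of class `hill_null`: long data.frame with columns
#'   `comparison, sample_a, sample_b, q, observed, null_mean, null_sd`.
#' @export
hill_null_expectation <- function(table, groups, comparisons = NULL,
                                  q_grid = seq(0, 3, by = 0.25),
                                  n_iter = 999,
                                  viewpoint = c("regional", "local"),
                                  seed = NULL) {
  viewpoint <- match.arg(viewpoint)
  if (n_iter < 1) stop("n_iter must be >= 1")
  table <- validate_count_table(table)
  groups <- .match_groups(groups, table)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(comparisons)) {
    gl <- sort(unique(groups))
    comparisons <- list()
    if (length(gl) > 1)
      for (i in seq_len(length(gl) - 1))
        for (j in seq(i + 1, length(gl)))
          comparisons[[length(comparisons) + 1]] <- c(gl[i], gl[j])
  }
  if (length(comparisons) == 0) stop("no group comparisons requested")
  kernel <- .null_kernel(table)
  rel <- to_relative(table)
  S <- rowSums(table > 0)
  N <- rowSums(table)
  rows <- list()
  for (cmp in comparisons) {
    if (!all(cmp %in% groups))
      stop("unknown group label in comparison: ", paste(cmp, collapse = ":"))
    sa <- rownames(table)[groups == cmp[1]]
    sb <- rownames(table)[groups == cmp[2]]
    cmp_label <- paste(cmp, collapse = ":")
    for (a in sa) for (b in sb) {
      obs <- vapply(q_grid, function(q)
        hill_dissimilarity(rel[a, ], rel[b, ], q, viewpoint), numeric(1))
      nulls <- matrix(NA_real_, n_iter, length(q_grid))
      for (it in seq_len(n_iter)) {
        na_ <- .null_sample(kernel, S[a], N[a])
        nb_ <- .null_sample(kernel, S[b], N[b])
        ra <- na_ / sum(na_); rb <- nb_ / sum(nb_)
        nulls[it, ] <- vapply(q_grid, function(q)
          hill_dissimilarity(ra, rb, q, viewpoint), numeric(1))
      }
      rows[[length(rows) + 1]] <- data.frame(
        comparison = cmp_label, sample_a = a, sample_b = b, q = q_grid,
        observed = obs,
        null_mean = colMeans(nulls),
        null_sd = apply(nulls, 2, stats::sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("hill_null", "data.frame"),
            n_iter = n_iter, viewpoint = viewpoint)
}

# Accept a groups vector either positional or named by sample id.
.match_groups <- function(groups, table) {
  if (!is.null(names(groups))) {
    missing <- setdiff(rownames(table), names(groups))
    if (length(missing) > 0)
      stop("samples without group label: ", paste(missing, collapse = ", "))
    groups <- groups[rownames(table)]
  } else if (length(groups) != nrow(table)) {
    stop("groups must have one entry per sample")
  }
  as.character(groups)
}

#' Average observed and null Hill curves for one group comparison
#'
#' @param result a `hill_null` object.
#' @param comparison length-2 character vector (group order is irrelevant).
#' @return data.frame with `q, observed, null_mean, null_sd` averaged over
#'   all between-group sample pairs.
#' @export
summarize_hill_curves <- function(result, comparison) {
  stopifnot(inherits(result, "hill_null"))
  lab <- c(paste(comparison, collapse = ":"),
           paste(rev(comparison), collapse = ":"))
  sub <- result[result$comparison %in% lab, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown comparison: ", lab[1])
  agg <- stats::aggregate(sub[c("observed", "null_mean", "null_sd")],
                          by = list(q = sub$q), FUN = mean)
  agg[order(agg$q), ]
}

#' @export
print.hill_null <- function(x, ...) {
  cat("Hill dissimilarity null analysis (", attr(x, "viewpoint"),
      " viewpoint, ", attr(x, "n_iter"), " null iterations)\n", sep = "")
  cat(length(unique(x$comparison)), "comparison(s),",
      length(unique(paste(x$sample_a, x$sample_b))), "sample pair(s),",
      length(unique(x$q)), "diversity orders\n")
  invisible(x)
}

#' @export
plot.hill_null <- function(x, comparison = NULL, ...) {
  if (is.null(comparison)) {
    comparison <- strsplit(unique(x$comparison)[1], ":")[[1]]
  }
  cur <- summarize_hill_curves(x, comparison)
  graphics::plot(cur$q, cur$observed, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "diversity order q", ylab = "dissimilarity", ...)
  graphics::lines(cur$q, cur$null_mean, lty = 2)
  graphics::legend("bottomright", c("observed", "null expectation"),
                   lty = c(1, 2), lwd = c(2, 1), bty = "n")
  invisible(cur)
}
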