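# Taxa-function robustness: perturb a sample's taxonomic profile many
# times, measure the taxonomic shift t (weighted UniFrac) against the
# functional shift f (cosine dissimilarity of the community function
# profile), and fit ln(f) = -a + b ln(t). The attenuation a (high a =
# functional shifts stay small as taxonomy moves — strong robustness via
# functional overlap) and buffering b (how large a perturbation must be
# before functional shift becomes noticeable) summarize each sample.
# Five gene distribution features (GDFs) account for robustness
# differences between communities.

#' Community function profile
#'
#' Abundance-weighted sum of genome copy numbers: for each function k,
#' `sum_s p_s * copynum[s, k]`.
#'
#' @param p named relative-abundance vector.
#' @param funcs OTUs x functions copy-number matrix.
#' @return named function-abundance vector.
#' @export
community_function_profile <- function(p, funcs) {
  common <- intersect(names(p)[p > 0], rownames(funcs))
  if (length(common) == 0) stop("no overlap between community and function table")
  drop(p[common] %*% funcs[common, , drop = FALSE])
}

#' Generate removal perturbations of a sample
#'
#' Each perturbation removes k taxa (k drawn uniformly in `1..S-1`, so
#' magnitudes span small to near-total) chosen uniformly at random, and
#' renormalizes the remainder; with `mode = "replace"` the removed share is
#' instead reassigned proportionally to a metacommunity pool.
#'
#' @param p named relative-abundance vector with richness >= 2.
#' @param n_perturb number of perturbations (default 100).
#' @param mode `"remove"` (default) or `"replace"`.
#' @param pool metacommunity relative abundances (required for
#'   `"replace"`).
#' @param seed optional integer seed.
#' @return list of perturbed relative-abundance vectors (same axis as `p`).
#' @export
perturb_sample <- function(p, n_perturb = 100, mode = c("remove", "replace"),
                           pool = NULL, seed = NULL) {
  mode <- match.arg(mode)
  present <- which(p > 0)
  S <- length(present)
  if (S < 2) stop("sample richness must be >= 2")
  if (mode == "replace" && is.null(pool))
    stop("replace mode needs a metacommunity pool")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_perturb), function(i) {
    k <- sample.int(S - 1, 1)
    drop_idx <- present[sample.int(S, k)]
    q <- p
    removed <- sum(q[drop_idx])
    q[drop_idx] <- 0
    if (mode == "remove") {
      q / sum(q)
    } else {
      w <- pool[names(p)]
      w[is.na(w)] <- 0
      w[drop_idx] <- 0
      if (sum(w) > 0) q <- q + removed * w / sum(w)
      q / sum(q)
    }
  })
}

#' Taxonomic shift of a perturbation
#'
#' Weighted normalized UniFrac (Generalized UniFrac with `alpha = 1`)
#' between the original and perturbed profiles.
#'
#' @param p,p_perturbed relative-abundance vectors.
#' @param tree rooted `phylo`.
#' @return shift in `[0, 1]`.
#' @export
taxonomic_shift <- function(p, p_perturbed, tree) {
  generalized_unifrac(p, p_perturbed, tree, alpha = 1)
}

#' Functional shift between two function profiles
#'
#' One minus the cosine similarity; scale-invariant in either argument.
#'
#' @param F1,F2 non-negative function-abundance vectors.
#' @return shift in `[0, 1]`, or `NA` if either vector is all-zero.
#' @export
functional_shift <- function(F1, F2) {
  n1 <- sqrt(sum(F1^2)); n2 <- sqrt(sum(F2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  d <- 1 - sum(F1 * F2) / (n1 * n2)
  if (d < 1e-12) d <- 0 # collinear profiles: exact zero, not fp noise
  min(max(d, 0), 1)
}

#' Fit the attenuation/buffering regression
#'
#' Ordinary least squares of `ln(f)` on `ln(t)` over perturbations with
#' `t > 0` and `f > 0`; attenuation `a = -intercept`, buffering
#' `b = slope`. When more than half of the points with `t > 0` have
#' `f = 0` (the functional profile did not move at all — very high
#' robustness) the fit is flagged degenerate and `a` is reported as
#' censored-high (`Inf`).
#'
#' @param t,f numeric vectors of taxonomic and functional shifts.
#' @return list with `a`, `b`, `r_squared`, `n_points_used`, `degenerate`.
#' @export
fit_robustness <- function(t, f) {
  if (length(t) != length(f)) stop("t and f must have equal length")
  ok_t <- which(t > 0 & !is.na(f))
  zero_f <- sum(f[ok_t] == 0)
  if (length(ok_t) > 0 && zero_f > 0.5 * length(ok_t)) {
    return(list(a = Inf, b = NA_real_, r_squared = NA_real_,
                n_points_used = 0L, degenerate = TRUE))
  }
  use <- which(t > 0 & f > 0 & is.finite(t) & is.finite(f))
  if (length(use) < 5)
    stop("need >= 5 perturbations with positive taxonomic and functional shift")
  fit <- stats::lm(log(f[use]) ~ log(t[use]))
  cf <- unname(stats::coef(fit))
  list(a = -cf[1], b = cf[2],
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n_points_used = length(use), degenerate = FALSE)
}

#' Gene distribution features of a community
#'
#' Five abundance-weighted genome statistics:
#' * `avg_genome_size`: `sum_s p_s |v_s|_1`;
#' * `genome_size_variability`: abundance-weighted SD of genome sizes;
#' * `avg_functional_dissimilarity`: abundance-pair-weighted mean cosine
#'   dissimilarity between the copy vectors of distinct present genomes;
#' * `avg_functional_redundancy`: mean number of present genomes carrying
#'   a function, weighted by the community abundance of that function;
#' * `unique_function_abundance`: fraction of the community function
#'   profile contributed by functions carried by exactly one present
#'   taxon.
#'
#' @param p named relative-abundance vector.
#' @param funcs OTUs x functions copy-number matrix.
#' @return named numeric vector of the five features
#'   (`avg_functional_dissimilarity` is `NA` for single-taxon
#'   communities).
#' @export
gene_distribution_features <- function(p, funcs) {
  common <- intersect(names(p)[p > 0], rownames(funcs))
  if (length(common) == 0) stop("no overlap between community and function table")
  w <- p[common] / sum(p[common])
  V <- funcs[common, , drop = FALSE]
  sizes <- rowSums(V)
  avg_size <- sum(w * sizes)
  size_var <- sqrt(sum(w * (sizes - avg_size)^2))
  n <- length(common)
  if (n == 1) {
    fdis <- NA_real_
  } else {
    norms <- sqrt(rowSums(V^2))
    C <- (V %*% t(V)) / outer(norms, norms)
    Dis <- 1 - C
    W <- outer(w, w)
    diag(W) <- 0
    fdis <- sum(W * Dis) / sum(W)
  }
  profile <- drop(w %*% V)
  carriers <- colSums(V > 0)
  carried <- which(carriers > 0 & profile > 0)
  redund <- if (length(carried) == 0) 0 else
    sum(profile[carried] * carriers[carried]) / sum(profile[carried])
  uniq <- which(carriers == 1)
  uniq_ab <- if (sum(profile) == 0) 0 else sum(profile[uniq]) / sum(profile)
  c(avg_genome_size = avg_size,
    genome_size_variability = size_var,
    avg_functional_dissimilarity = fdis,
    avg_functional_redundancy = redund,
    unique_function_abundance = uniq_ab)
}

#' Per-category robustness fits for one sample
#'
#' Reuses one perturbation set across categories, computing the functional
#' shift on the sub-vector of functions in each category.
#'
#' @param p named relative-abundance vector.
#' @param tree rooted `phylo`.
#' @param funcs OTUs x functions matrix.
#' @param category_map named character vector: function id -> category.
#' @param n_perturb perturbations (default 100).
#' @param seed optional integer seed.
#' @return data.frame with one row per category (`category, a, b,
#'   r_squared, n_points_used, degenerate`).
#' @export
robustness_by_category <- function(p, tree, funcs, category_map,
                                   n_perturb = 100, seed = NULL) {
  cats <- split(names(category_map), unname(category_map))
  cats <- lapply(cats, intersect, colnames(funcs))
  if (all(lengths(cats) == 0)) stop("category map covers no functions")
  cats <- cats[lengths(cats) > 0]
  perts <- perturb_sample(p, n_perturb, seed = seed)
  tshift <- vapply(perts, function(q) taxonomic_shift(p, q, tree), numeric(1))
  F0 <- community_function_profile(p, funcs)
  Fp <- lapply(perts, community_function_profile, funcs = funcs)
  out <- lapply(names(cats), function(cn) {
    ks <- cats[[cn]]
    fshift <- vapply(Fp, function(Fq) functional_shift(F0[ks], Fq[ks]),
                     numeric(1))
    fit <- tryCatch(fit_robustness(tshift, fshift), error = function(e)
      list(a = NA_real_, b = NA_real_, r_squared = NA_real_,
           n_points_used = 0L, degenerate = NA))
    data.frame(category = cn, a = fit$a, b = fit$b,
               r_squared = fit$r_squared, n_points_used = fit$n_points_used,
               degenerate = fit$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Taxa-function robustness profile of every sample
#'
#' @param table samples x OTUs count matrix.
#' @param tree rooted `phylo` covering the table's OTUs.
#' @param funcs OTUs x functions copy-number matrix.
#' @param n_perturb perturbations per sample (default 100).
#' @param categories optional named character vector (function ->
#'   category) for per-category fits.
#' @param seed optional integer seed.
#' @return object of class `robustness_profile`: `samples` data.frame
#'   (sample, a, b, r_squared, n_points_used, degenerate + the five GDFs)
#'   and optionally `categories` (long per-sample-per-category fits).
#' @export
robustness <- function(table, tree, funcs, n_perturb = 100,
                       categories = NULL, seed = NULL) {
  bundle <- align_inputs(table, tree, funcs = funcs)
  table <- bundle$table
  if (!is.null(seed)) set.seed(seed)
  # restrict each sample to OTUs with functional annotation
  sub <- table[, rownames(bundle$funcs), drop = FALSE]
  rs <- rowSums(sub)
  if (any(rs == 0)) {
    warning("dropping ", sum(rs == 0),
            " sample(s) with no functionally annotated OTUs")
    sub <- sub[rs > 0, , drop = FALSE]
  }
  rel <- to_relative(sub)
  tree <- ape::keep.tip(bundle$tree, rownames(bundle$funcs))
  funcs <- bundle$funcs
  rows <- list()
  cat_rows <- list()
  for (s in rownames(rel)) {
    p <- rel[s, ]
    if (sum(p > 0) < 2) {
      rows[[s]] <- data.frame(sample = s, a = NA_real_, b = NA_real_,
                              r_squared = NA_real_, n_points_used = 0L,
                              degenerate = NA,
                              as.list(gene_distribution_features(p, funcs)),
                              stringsAsFactors = FALSE)
      next
    }
    perts <- perturb_sample(p, n_perturb)
    tshift <- vapply(perts, function(q) taxonomic_shift(p, q, tree),
                     numeric(1))
    F0 <- community_function_profile(p, funcs)
    fshift <- vapply(perts, function(q)
      functional_shift(F0, community_function_profile(q, funcs)), numeric(1))
    fit <- tryCatch(fit_robustness(tshift, fshift), error = function(e)
      list(a = NA_real_, b = NA_real_, r_squared = NA_real_,
           n_points_used = 0L, degenerate = NA))
    gdf <- gene_distribution_features(p, funcs)
    rows[[s]] <- data.frame(sample = s, a = fit$a, b = fit$b,
                            r_squared = fit$r_squared,
                            n_points_used = fit$n_points_used,
                            degenerate = fit$degenerate,
                            as.list(gdf), stringsAsFactors = FALSE)
    if (!is.null(categories)) {
      cr <- robustness_by_category(p, tree, funcs, categories, n_perturb)
      cr <- data.frame(sample = s, cr, stringsAsFactors = FALSE)
      cat_rows[[s]] <- cr
    }
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  out <- list(samples = samples,
              categories = if (length(cat_rows) > 0)
                do.call(rbind, c(cat_rows, make.row.names = FALSE)) else NULL,
              n_perturb = n_perturb)
  class(out) <- "robustness_profile"
  out
}

#' @export
print.robustness_profile <- function(x, ...) {
  cat("Taxa-function robustness (", x$n_perturb,
      " perturbations per sample)\n", sep = "")
  ok <- is.finite(x$samples$a)
  cat(sprintf("  %d sample(s); attenuation a: median %.3f, buffering b: median %.3f\n",
              nrow(x$samples), stats::median(x$samples$a[ok]),
              stats::median(x$samples$b[ok])))
  if (any(!ok)) cat("  ", sum(!ok), "degenerate sample(s) (censored-high a)\n")
  invisible(x)
}

#' @export
summary.robustness_profile <- function(object, ...) object$samples

#' Principal-coordinate ordination of gene distribution features
#'
#' Standardizes the GDF columns (dropping constant ones with a warning),
#' embeds samples by classical multidimensional scaling of Euclidean
#' distances, and reports per-feature loadings (correlation of each
#' feature with each axis) and percent variance per axis.
#'
#' @param gdf_table samples x features numeric matrix or data.frame (e.g.
#'   the GDF columns of a [robustness()] result).
#' @param k number of axes (default 2).
#' @return list with `points`, `loadings`, `percent_variance`.
#' @export
gdf_ordination <- function(gdf_table, k = 2) {
  X <- as.matrix(gdf_table)
  if (nrow(X) < 3) stop("need >= 3 samples to ordinate")
  keep <- apply(X, 2, function(col) stats::sd(col, na.rm = TRUE) > 0)
  if (any(!keep))
    warning("dropping constant feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  Z <- scale(X)
  k <- min(k, nrow(Z) - 1, ncol(Z))
  mds <- stats::cmdscale(stats::dist(Z), k = k, eig = TRUE)
  pts <- mds$points
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  pos <- mds$eig[mds$eig > 1e-12]
  pct <- 100 * mds$eig[seq_len(k)] / sum(pos)
  loadings <- stats::cor(Z, pts)
  list(points = pts, loadings = loadings,
       percent_variance = pct)
}
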