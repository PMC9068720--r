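# BVSTEP subset search: find a small OTU subset whose between-sample
# Bray-Curtis pattern rank-correlates (Spearman, Mantel-style without a
# permutation test) with the pattern of the full table above a target rho.

#' Condensed Bray-Curtis distance vector for an OTU subset
#'
#' Distances are computed on the (optionally transformed) relative
#' abundances of the subset columns, without renormalizing within the
#' subset; sample pairs where both samples have zero subset abundance get
#' distance 1 by convention.
#'
#' @param table samples x OTUs count matrix.
#' @param otu_subset character vector of OTU ids (default: all).
#' @param transform `"none"` (default), `"sqrt"` or `"log"` (log1p),
#'   applied to relative abundances before Bray-Curtis.
#' @return condensed distance vector over all unordered sample pairs, in
#'   the order of `utils::combn(samples, 2)` (same as `stats::dist`).
#' @export
distance_vector <- function(table, otu_subset = colnames(table),
                            transform = c("none", "sqrt", "log")) {
  transform <- match.arg(transform)
  if (length(otu_subset) == 0) stop("empty OTU subset")
  missing <- setdiff(otu_subset, colnames(table))
  if (length(missing) > 0) stop("unknown OTU(s): ", paste(missing, collapse = ", "))
  X <- .bv_transform(to_relative(table), transform)[, otu_subset, drop = FALSE]
  d <- as.vector(suppressWarnings(vegan::vegdist(X, method = "bray",
                                                 na.rm = FALSE)))
  if (anyNA(d)) {
    message("distance_vector: ", sum(is.na(d)), " sample pair(s) with no ",
            "subset counts set to distance 1 by convention")
    d[is.na(d)] <- 1
  }
  d
}

.bv_transform <- function(X, transform) {
  switch(transform, none = X, sqrt = sqrt(X), log = log1p(X))
}

# Pair-wise contribution matrices so candidate subsets can be scored
# incrementally: bray(S) = rowSums(ABS[, S]) / rowSums(SUM[, S]).
.bv_precompute <- function(X) {
  ns <- nrow(X)
  pr <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  # order pairs as dist/vegdist does: column-major lower triangle
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  ABS <- abs(X[pr[, 1], , drop = FALSE] - X[pr[, 2], , drop = FALSE])
  SUM <- X[pr[, 1], , drop = FALSE] + X[pr[, 2], , drop = FALSE]
  list(ABS = ABS, SUM = SUM)
}

# rho between the full-table ranks and each candidate subset column-set.
.bv_rho_many <- function(pc, base_num, base_den, cand_cols, full_rank, sign) {
  NUM <- base_num + sign * pc$ABS[, cand_cols, drop = FALSE]
  DEN <- base_den + sign * pc$SUM[, cand_cols, drop = FALSE]
  D <- NUM / DEN
  D[DEN == 0] <- 1
  suppressWarnings(stats::cor(full_rank, apply(D, 2, rank),
                              method = "pearson"))[1, ]
}

#' BVSTEP search for a Bray-Curtis-preserving OTU subset
#'
#' Forward-addition/backward-elimination hill climb on the Spearman rank
#' correlation between the subset and full-table Bray-Curtis distance
#' vectors, from several random starting subsets. Additions must strictly
#' improve rho; eliminations are accepted whenever they do not decrease it
#' (preferring the smaller subset on ties). The best subset across
#' restarts is returned (reaching `rho_target` preferred, then smaller
#' size, then higher rho).
#'
#' @param table samples x OTUs count matrix (>= 4 samples).
#' @param rho_target stopping correlation in `(0, 1]` (default 0.95).
#' @param max_restarts random restarts (default 10).
#' @param init_size size of each random starting subset (default 5).
#' @param transform see [distance_vector()].
#' @param seed optional integer seed.
#' @return object of class `bvstep`: `selected` OTU ids, `rho`, `trace`
#'   data.frame (restart, step, action, otu, rho, size), `rho_target`.
#' @export
bvstep_search <- function(table, rho_target = 0.95, max_restarts = 10,
                          init_size = 5, transform = c("none", "sqrt", "log"),
                          seed = NULL) {
  transform <- match.arg(transform)
  if (rho_target <= 0 || rho_target > 1) stop("rho_target must be in (0, 1]")
  table <- validate_count_table(table)
  if (nrow(table) < 4) stop("need >= 4 samples")
  if (!is.null(seed)) set.seed(seed)
  X <- .bv_transform(to_relative(table), transform)
  otus <- colnames(X)
  n_otu <- length(otus)
  if (n_otu == 1) {
    return(structure(list(selected = otus, rho = 1,
                          trace = data.frame(restart = 1L, step = 0L,
                                             action = "init", otu = otus,
                                             rho = 1, size = 1L),
                          rho_target = rho_target), class = "bvstep"))
  }
  pc <- .bv_precompute(X)
  full <- rowSums(pc$ABS) / rowSums(pc$SUM)
  full[rowSums(pc$SUM) == 0] <- 1
  full_rank <- rank(full)
  rho_of <- function(sel) {
    num <- rowSums(pc$ABS[, sel, drop = FALSE])
    den <- rowSums(pc$SUM[, sel, drop = FALSE])
    d <- num / den
    d[den == 0] <- 1
    suppressWarnings(stats::cor(full_rank, rank(d)))
  }
  best <- NULL
  trace <- list()
  init_size <- min(init_size, n_otu)
  for (r in seq_len(max_restarts)) {
    sel <- sample(otus, init_size)
    rho <- rho_of(sel)
    step <- 0L
    trace[[length(trace) + 1]] <- data.frame(
      restart = r, step = step, action = "init", otu = NA_character_,
      rho = rho, size = length(sel), stringsAsFactors = FALSE)
    repeat {
      moved <- FALSE
      # backward elimination: drop whenever rho does not decrease
      if (length(sel) > 1) {
        repeat {
          base_num <- rowSums(pc$ABS[, sel, drop = FALSE])
          base_den <- rowSums(pc$SUM[, sel, drop = FALSE])
          rhos <- .bv_rho_many(pc, base_num, base_den, sel, full_rank, -1)
          ok <- which(rhos >= rho - 1e-10)
          if (length(ok) == 0 || length(sel) == 1) break
          j <- ok[which.max(rhos[ok])]
          rho <- rho_of(sel[-j])
          step <- step + 1L
          trace[[length(trace) + 1]] <- data.frame(
            restart = r, step = step, action = "drop", otu = sel[j],
            rho = rho, size = length(sel) - 1L, stringsAsFactors = FALSE)
          sel <- sel[-j]
          moved <- TRUE
          if (length(sel) == 1) break
        }
      }
      # forward addition: add the best strict improvement (only while the
      # target has not been reached — minimal subsets are preferred)
      if (rho < rho_target) {
        out <- setdiff(otus, sel)
        if (length(out) > 0) {
          base_num <- rowSums(pc$ABS[, sel, drop = FALSE])
          base_den <- rowSums(pc$SUM[, sel, drop = FALSE])
          rhos <- .bv_rho_many(pc, base_num, base_den, out, full_rank, +1)
          j <- which.max(rhos)
          if (is.finite(rhos[j]) && rhos[j] > rho + 1e-10) {
            sel <- c(sel, out[j])
            rho <- rho_of(sel)
            step <- step + 1L
            trace[[length(trace) + 1]] <- data.frame(
              restart = r, step = step, action = "add", otu = out[j],
              rho = rho, size = length(sel), stringsAsFactors = FALSE)
            moved <- TRUE
          }
        }
      }
      if (!moved || step > 50 * n_otu) break
    }
    cand <- list(selected = sel, rho = rho)
    if (is.null(best) || .bv_better(cand, best, rho_target)) best <- cand
  }
  structure(list(selected = sort(best$selected), rho = best$rho,
                 trace = do.call(rbind, trace), rho_target = rho_target),
            class = "bvstep")
}

# Preference order: meet the target with the smallest subset, else highest rho.
.bv_better <- function(a, b, target) {
  am <- a$rho >= target; bm <- b$rho >= target
  if (am != bm) return(am)
  if (am) {
    if (length(a$selected) != length(b$selected))
      return(length(a$selected) < length(b$selected))
    return(a$rho > b$rho)
  }
  a$rho > b$rho
}

#' @export
print.bvstep <- function(x, ...) {
  cat("BVSTEP subset search (target rho = ", x$rho_target, ")\n", sep = "")
  cat(sprintf("  selected %d OTU(s), Spearman rho = %.4f\n",
              length(x$selected), x$rho))
  cat("  ", paste(utils::head(x$selected, 12), collapse = ", "),
      if (length(x$selected) > 12) ", ..." else "", "\n", sep = "")
  invisible(x)
}
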