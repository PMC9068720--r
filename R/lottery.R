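# Competitive lottery model: within a genus-level clade, a sample's
# "winner" is the member OTU holding more than 90% of the clade's reads in
# that sample. Winner prevalence is the fraction of clade-bearing samples
# with a winner; winner diversity is the normalized Shannon entropy of
# winner identities across samples. Clades with prevalence > 0.75 and
# diversity > 0.25 behave lottery-like (stochastic winner replacement).

#' Partition OTUs into genus-level clades
#'
#' @param tax taxonomy data.frame (rownames = OTU ids, with a `genus`
#'   column; see [read_taxonomy()]) or a named character vector of genus
#'   labels.
#' @param table samples x OTUs count matrix; only its OTUs are used.
#' @param min_clade_otus clades with fewer members are flagged trivial
#'   (their winners are structurally forced) but retained.
#' @return list with `clades` (named list genus -> OTU ids), `trivial`
#'   (logical per clade) and `n_unannotated` (OTUs excluded for missing
#'   genus, reported via a message).
#' @export
build_clades <- function(tax, table, min_clade_otus = 2) {
  otus <- colnames(table)
  genus <- if (is.data.frame(tax)) {
    g <- tax[["genus"]]
    names(g) <- rownames(tax)
    g
  } else tax
  g <- genus[otus]
  names(g) <- otus
  unannot <- is.na(g) | g == ""
  if (any(unannot))
    message("build_clades: ", sum(unannot),
            " OTU(s) without genus annotation excluded")
  g <- g[!unannot]
  if (length(g) == 0) stop("no genus-annotated OTUs; empty clade partition")
  clades <- split(names(g), unname(g))
  trivial <- vapply(clades, length, integer(1)) < min_clade_otus
  list(clades = clades, trivial = trivial, n_unannotated = sum(unannot))
}

#' Detect the lottery winner within a clade in one sample
#'
#' @param clade_abundances named abundance vector of the clade members in
#'   one sample (any scale; only within-clade proportions matter).
#' @param threshold winner must hold strictly more than this share of the
#'   clade total (default 0.9).
#' @return the winning OTU id, or `NA` if no member exceeds the threshold.
#' @export
detect_winner <- function(clade_abundances, threshold = 0.9) {
  tot <- sum(clade_abundances)
  if (tot <= 0) stop("clade absent from sample; not evaluable")
  share <- clade_abundances / tot
  w <- which(share > threshold)
  if (length(w) == 0) return(NA_character_)
  names(clade_abundances)[w[1]]
}

#' Winner prevalence across evaluated samples
#'
#' @param winners character vector of winner ids per evaluated sample
#'   (`NA` = no winner in that sample).
#' @return fraction of evaluated samples with a winner, in `[0, 1]`.
#' @export
winner_prevalence <- function(winners) {
  if (length(winners) == 0) stop("no evaluated samples")
  mean(!is.na(winners))
}

#' Normalized winner diversity
#'
#' Shannon entropy of the winner-identity frequency distribution,
#' normalized by `log(number of distinct winners)`; 0 (by convention) when
#' a single OTU wins everywhere, approaching 1 when wins are spread evenly
#' across member OTUs.
#'
#' @param winners character vector of winner ids (NAs ignored).
#' @return normalized diversity in `[0, 1]`, or `NA` if there are no wins.
#' @export
winner_diversity <- function(winners) {
  w <- winners[!is.na(winners)]
  if (length(w) == 0) return(NA_real_)
  f <- table(w) / length(w)
  if (length(f) == 1) return(0)
  h <- -sum(f * log(f))
  h / log(length(f))
}

#' Competitive lottery report per clade and time group
#'
#' @param table samples x OTUs count matrix.
#' @param tax taxonomy (see [build_clades()]).
#' @param groups time-group label per sample (or named by sample id), e.g.
#'   the week of sampling.
#' @param threshold winner share threshold (default 0.9, strict).
#' @param presence_floor a clade is evaluated in a sample only when its
#'   relative abundance there is at least this floor (default 0.001).
#' @param min_clade_otus see [build_clades()]; single-OTU clades are
#'   reported but never flagged lottery-like.
#' @return object of class `lottery_report`: data.frame with one row per
#'   clade x time group (`clade, group, n_evaluated, prevalence, diversity,
#'   winners, trivial, lottery_like`). Clades absent from every sample of a
#'   group get `NA` prevalence/diversity.
#' @export
lottery_report <- function(table, tax, groups, threshold = 0.9,
                           presence_floor = 0.001, min_clade_otus = 2) {
  table <- validate_count_table(table)
  groups <- .match_groups(groups, table)
  cl <- build_clades(tax, table, min_clade_otus)
  rel <- to_relative(table)
  rows <- list()
  for (ci in seq_along(cl$clades)) {
    clade <- names(cl$clades)[ci]
    members <- cl$clades[[ci]]
    sub <- rel[, members, drop = FALSE]
    clade_tot <- rowSums(sub)
    for (g in unique(groups)) {
      ss <- which(groups == g & clade_tot >= presence_floor)
      if (length(ss) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          clade = clade, group = g, n_evaluated = 0L,
          prevalence = NA_real_, diversity = NA_real_, winners = "",
          trivial = cl$trivial[ci], lottery_like = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      winners <- vapply(ss, function(s)
        detect_winner(stats::setNames(as.numeric(sub[s, ]), members),
                      threshold), character(1))
      prev <- winner_prevalence(winners)
      div <- winner_diversity(winners)
      wtab <- table(winners[!is.na(winners)])
      wstr <- paste(sprintf("%s(%d)", names(wtab), as.integer(wtab)),
                    collapse = "+")
      rows[[length(rows) + 1]] <- data.frame(
        clade = clade, group = g, n_evaluated = length(ss),
        prevalence = prev, diversity = div, winners = wstr,
        trivial = cl$trivial[ci],
        lottery_like = !cl$trivial[ci] && !is.na(div) &&
          prev > 0.75 && div > 0.25,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("lottery_report", "data.frame"),
            threshold = threshold, presence_floor = presence_floor,
            n_unannotated = cl$n_unannotated)
}

#' @export
print.lottery_report <- function(x, ...) {
  cat("Competitive lottery report (winner share > ",
      attr(x, "threshold") * 100, "% of clade)\n", sep = "")
  df <- as.data.frame(x)
  print(df[, c("clade", "group", "n_evaluated", "prevalence", "diversity",
               "lottery_like")], row.names = FALSE, digits = 3)
  invisible(x)
}
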