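# Synthetic communities with known assembly regime. The drift kernel is
# Wright-Fisher multinomial resampling of a fixed-size community, with
# migration from a lognormal metacommunity and (for selection regimes)
# stabilizing selection toward a focal lineage's phylogenetic neighborhood,
# so that selection is phylogenetically autocorrelated — the property the
# beta-nearest-taxon statistics are designed to detect. Every simulator is
# a pure function of (parameters, seed).

#' Simulate an ultrametric birth-death phylogeny
#'
#' @param n_tips number of tips (>= 3), labelled `OTU_1..OTU_n`.
#' @param birth_rate,death_rate birth-death rates, `birth_rate > death_rate >= 0`.
#' @param seed integer seed.
#' @return ultrametric `phylo`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, death_rate = 0, seed = 1) {
  if (n_tips < 3) stop("n_tips must be >= 3")
  if (!(birth_rate > death_rate) || death_rate < 0)
    stop("need birth_rate > death_rate >= 0")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = death_rate)
  tree$tip.label <- paste0("OTU_", seq_len(n_tips))
  tree
}

#' Simulate a lognormal metacommunity abundance vector
#'
#' @param tree `phylo` defining the species pool (its tips).
#' @param meanlog,sdlog lognormal parameters; `sdlog = 0` gives a uniform
#'   vector.
#' @param seed integer seed.
#' @return strictly positive named vector summing to 1.
#' @export
simulate_metacommunity <- function(tree, meanlog = 0, sdlog = 1.2, seed = 1) {
  if (sdlog < 0) stop("sdlog must be >= 0")
  set.seed(seed)
  n <- length(tree$tip.label)
  x <- stats::rlnorm(n, meanlog, sdlog)
  names(x) <- tree$tip.label
  x / sum(x)
}

#' Simulation configuration
#'
#' Bundles the parameters of [simulate_community_series()] with validation.
#' Defaults emulate a feeding-trial-style design: several treatment groups
#' sampled destructively at three time points, thousands of reads per
#' sample, and effect sizes strong enough that each assembly regime is
#' expressed in the statistics designed to detect it.
#'
#' @param seed integer seed (all randomness derives from it).
#' @param groups character vector of group labels.
#' @param n_timepoints number of ordered time points.
#' @param n_samples samples per group per time point.
#' @param library_size reads per emitted sample.
#' @param community_size number of individuals in the Wright-Fisher
#'   community; `NULL` (default) resolves per regime: 1000 under
#'   homogeneous selection (drift must turn over clade members between
#'   samples), 5000 otherwise.
#' @param regime one of `"neutral"`, `"homogeneous_selection"`,
#'   `"variable_selection"`, `"dispersal_limited"`.
#' @param selection_strength phylogenetic-neighborhood selection strength
#'   (>= 0; 0 reduces a selection regime to neutral drift bit-for-bit).
#' @param migration migration rate m from the metacommunity in `[0, 1]`.
#'   `NULL` (default) resolves per regime: 0.5 for neutral, 0 otherwise
#'   (selection and dispersal limitation act without homogenizing
#'   dispersal).
#' @param n_generations Wright-Fisher generations per time-point
#'   interval; `NULL` (default) resolves per regime: 50 under homogeneous
#'   selection, 20 otherwise.
#' @param founder_size number of founder OTUs per sample (dispersal
#'   limitation and selection regimes); `NULL` = 60% of the pool.
#' @param founder_abund_sd lognormal SD of the per-sample scrambling of
#'   founder abundances under dispersal limitation (historical
#'   contingency; 0 disables).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       groups = paste0("G", 1:4),
                       n_timepoints = 3,
                       n_samples = 4,
                       library_size = 5000,
                       community_size = NULL,
                       regime = c("neutral", "homogeneous_selection",
                                  "variable_selection", "dispersal_limited"),
                       selection_strength = 2,
                       migration = NULL,
                       n_generations = NULL,
                       founder_size = NULL,
                       founder_abund_sd = 1.5) {
  regime <- match.arg(regime)
  if (is.null(community_size))
    community_size <- if (regime == "homogeneous_selection") 1000 else 5000
  if (is.null(n_generations))
    n_generations <- if (regime == "homogeneous_selection") 50 else 20
  stopifnot(n_timepoints >= 1, n_samples >= 1, library_size >= 1,
            community_size >= 1, n_generations >= 0,
            selection_strength >= 0, founder_abund_sd >= 0)
  if (is.null(migration))
    migration <- if (regime == "neutral") 0.5 else 0
  if (migration < 0 || migration > 1) stop("migration must be in [0, 1]")
  if (regime == "dispersal_limited") migration <- 0
  if (!is.null(founder_size) && founder_size < 1)
    stop("founder_size must be >= 1")
  structure(list(seed = seed, groups = groups, n_timepoints = n_timepoints,
                 n_samples = n_samples, library_size = library_size,
                 community_size = community_size, regime = regime,
                 selection_strength = selection_strength,
                 migration = migration, n_generations = n_generations,
                 founder_size = founder_size,
                 founder_abund_sd = founder_abund_sd),
            class = "sim_config")
}

#' Simulate a multi-group community time series under a known regime
#'
#' Each sample is an independent Wright-Fisher chain (destructive
#' sampling: one fish, one sample) of `community_size` individuals,
#' resampled multinomially for `n_generations * time_index` generations
#' with offspring probabilities `((1 - m) x/J + m meta) * w` and finally
#' sampled down to `library_size` reads. The regimes differ in
#' initialization and fitness `w`:
#'
#' * `neutral`: initialized from the metacommunity, `w = 1`; with high
#'   migration every sample stays a noisy draw from the metacommunity.
#' * `homogeneous_selection`: every sample starts from its own uniform
#'   founder subset and is filtered by phylogenetic-neighborhood
#'   stabilizing selection `w_s = exp(-strength (d(s, focal)/(2 dbar))^2)`
#'   toward one focal lineage shared by all groups (`d` patristic
#'   distance, `dbar` the mean tip-tip distance). The focal tip is the
#'   one with the densest phylogenetic neighborhood, so the favored set
#'   is a clade. Communities converge on that clade while founder subsets
#'   and drift make different samples carry different clade members.
#' * `variable_selection`: as above, but each group gets its own focal
#'   lineage, chosen greedily to maximize the minimum pairwise patristic
#'   distance between focals, so different groups are pushed onto
#'   phylogenetically distant clades.
#' * `dispersal_limited`: per-sample uniform founder subsets whose founder
#'   abundances are scrambled by a lognormal factor
#'   (`founder_abund_sd`) — historical contingency: which taxa arrived
#'   and prospered is decoupled from the regional pool — followed by
#'   neutral drift with `m = 0`.
#'
#' A `selection_strength` of 0 degrades either selection regime to the
#' neutral regime, reproducing it bit-for-bit under the same seed.
#'
#' @param tree `phylo` species pool.
#' @param metacommunity regional relative-abundance vector over the tips
#'   (see [simulate_metacommunity()]).
#' @param config a [sim_config()].
#' @return list with `table` (samples x OTUs counts), `metadata`
#'   (sample_id, time_point, group, group_time), and `ground_truth`
#'   (regime, focal tips, founders, config).
#' @export
simulate_community_series <- function(tree, metacommunity, config) {
  stopifnot(inherits(config, "sim_config"))
  meta <- metacommunity[tree$tip.label]
  if (anyNA(meta) || abs(sum(meta) - 1) > 1e-9)
    stop("metacommunity must cover all tree tips and sum to 1")
  set.seed(config$seed)
  n <- length(meta)
  J <- config$community_size
  m <- config$migration
  fs <- if (is.null(config$founder_size)) ceiling(0.6 * n) else
    min(config$founder_size, n)
  selection <- config$regime %in% c("homogeneous_selection",
                                    "variable_selection") &&
    config$selection_strength > 0
  regime <- if (selection || config$regime == "dispersal_limited")
    config$regime else "neutral"
  focal <- NULL
  fitness <- NULL
  if (selection) {
    D <- ape::cophenetic.phylo(tree)
    dbar <- mean(D[upper.tri(D)])
    if (config$regime == "homogeneous_selection") {
      # the focal lineage with the densest phylogenetic neighborhood:
      # the favored set is then a clade on any tree realization
      nn <- rowSums(D < 0.3 * dbar) - 1
      f <- which.max(nn)
      focal <- stats::setNames(rep(tree$tip.label[f], length(config$groups)),
                               config$groups)
    } else {
      f <- sample.int(n, 1)
      while (length(f) < length(config$groups)) {
        gap <- apply(D[f, , drop = FALSE], 2, min)
        f <- c(f, which.max(gap))
      }
      focal <- stats::setNames(tree$tip.label[f], config$groups)
    }
    fitness <- lapply(focal, function(ft)
      exp(-config$selection_strength * (D[ft, ] / (2 * dbar))^2))
  }
  samples <- list()
  info <- list()
  founders <- list()
  for (g in config$groups) {
    for (t in seq_len(config$n_timepoints)) {
      for (i in seq_len(config$n_samples)) {
        sid <- sprintf("%s_T%d_S%d", g, t, i)
        if (regime == "neutral") {
          x <- as.integer(stats::rmultinom(1, J, meta))
        } else {
          fo <- sample.int(n, fs)
          founders[[sid]] <- tree$tip.label[fo]
          p0 <- numeric(n)
          p0[fo] <- meta[fo]
          if (regime == "dispersal_limited" && config$founder_abund_sd > 0)
            p0[fo] <- p0[fo] *
              stats::rlnorm(fs, 0, config$founder_abund_sd)
          x <- as.integer(stats::rmultinom(1, J, p0 / sum(p0)))
        }
        gens <- config$n_generations * t
        w <- if (selection) fitness[[g]] else NULL
        if (gens > 0) {
          for (gen in seq_len(gens)) {
            pr <- (1 - m) * x / J + m * meta
            if (!is.null(w)) pr <- pr * w
            x <- as.integer(stats::rmultinom(1, J, pr / sum(pr)))
          }
        }
        y <- as.integer(stats::rmultinom(1, config$library_size, x / J))
        samples[[sid]] <- y
        info[[sid]] <- data.frame(sample_id = sid,
                                  time_point = paste0("T", t),
                                  group = g, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, samples)
  colnames(tab) <- tree$tip.label
  md <- do.call(rbind, info)
  md$time_point <- factor(md$time_point,
                          levels = paste0("T", seq_len(config$n_timepoints)),
                          ordered = TRUE)
  md$group_time <- paste(md$group, md$time_point, sep = "_")
  rownames(md) <- md$sample_id
  list(table = tab, metadata = md,
       ground_truth = list(regime = config$regime, focal = focal,
                           founders = founders, config = config))
}

#' Plant lottery-structured clades into a count table
#'
#' For each planted clade, in every sample where the clade has reads, one
#' member (the winner) is reassigned at least `winner_share` of the clade's
#' reads; the winner is either the same OTU in every sample
#' (`winner_mode = "fixed"`, diversity -> 0) or re-drawn uniformly per
#' sample (`"per_sample_random"`, diversity -> 1).
#'
#' @param table samples x OTUs count matrix.
#' @param n_clades,clade_size number and size of planted clades (uses the
#'   first `n_clades * clade_size` OTUs).
#' @param winner_mode `"fixed"` or `"per_sample_random"`.
#' @param winner_share minimum within-clade share of the winner
#'   (default 0.97).
#' @param seed integer seed.
#' @return list with `table` (modified counts), `taxonomy` (named genus
#'   vector covering the planted OTUs: `Clade_1`, `Clade_2`, ...) and
#'   `ground_truth` (members and per-sample winners per clade).
#' @export
plant_lottery_clades <- function(table, n_clades = 2, clade_size = 3,
                                 winner_mode = c("fixed", "per_sample_random"),
                                 winner_share = 0.97, seed = 1) {
  winner_mode <- match.arg(winner_mode)
  if (ncol(table) < n_clades * clade_size)
    stop("table needs at least n_clades * clade_size OTUs")
  set.seed(seed)
  tab <- table
  taxonomy <- character(0)
  truth <- list()
  for (ci in seq_len(n_clades)) {
    members <- colnames(tab)[((ci - 1) * clade_size + 1):(ci * clade_size)]
    genus <- paste0("Clade_", ci)
    taxonomy[members] <- genus
    fixed_winner <- members[1]
    winners <- stats::setNames(rep(NA_character_, nrow(tab)), rownames(tab))
    for (s in seq_len(nrow(tab))) {
      tot <- sum(tab[s, members])
      if (tot == 0) next
      winner <- if (winner_mode == "fixed") fixed_winner
      else sample(members, 1)
      rest <- setdiff(members, winner)
      loser_each <- floor(tot * (1 - winner_share) / length(rest))
      tab[s, rest] <- loser_each
      tab[s, winner] <- tot - loser_each * length(rest)
      winners[s] <- winner
    }
    truth[[genus]] <- list(members = members, winners = winners,
                           mode = winner_mode)
  }
  list(table = tab, taxonomy = taxonomy, ground_truth = truth)
}

#' Simulate a recruitment time series with known dispersion
#'
#' Taxa are added sequentially: the first uniformly at random, each later
#' one with probability proportional to `exp(D_true * z_s)`, z_s the
#' standardized mean patristic distance from candidate s to the taxa
#' already recruited. Consecutive recruits are grouped into time points.
#'
#' @param tree `phylo` species pool.
#' @param D_true true dispersion (finite; 0 = equiprobable recruitment).
#' @param n_timepoints number of time points.
#' @param taxa_per_step taxa recruited per time point.
#' @param seed integer seed.
#' @return list with `series` (a [detection_series()]-shaped object),
#'   `presence` (time points x taxa 0/1 matrix) and `ground_truth`
#'   (`D_true` and the full recruitment order).
#' @export
simulate_recruitment_series <- function(tree, D_true, n_timepoints,
                                        taxa_per_step, seed = 1) {
  if (!is.finite(D_true)) stop("D_true must be finite")
  n <- length(tree$tip.label)
  total <- n_timepoints * taxa_per_step
  if (total > n) stop("taxa pool exhausted: need ", total, " of ", n, " tips")
  set.seed(seed)
  D <- ape::cophenetic.phylo(tree)
  ord <- .recruit_order(D, integer(0), seq_len(n), 0)[1] # first uniform
  rest <- .recruit_order(D, ord, setdiff(seq_len(n), ord), D_true)
  order_full <- c(ord, rest)[seq_len(total)]
  new <- split(tree$tip.label[order_full],
               rep(seq_len(n_timepoints), each = taxa_per_step))
  names(new) <- paste0("T", seq_len(n_timepoints))
  presence <- matrix(0L, n_timepoints, n,
                     dimnames = list(names(new), tree$tip.label))
  seen <- character(0)
  for (t in seq_len(n_timepoints)) {
    seen <- union(seen, new[[t]])
    presence[t, seen] <- 1L
  }
  series <- structure(list(group = "sim", time_points = names(new),
                           new = new),
                      class = "detection_series")
  list(series = series, presence = presence,
       ground_truth = list(D_true = D_true,
                           order = tree$tip.label[order_full]))
}

#' Simulate a genome function copy-number table
#'
#' Controls functional redundancy through the number of genomes carrying
#' each function: under `"high"` most genomes carry most functions, under
#' `"low"` functions are mostly genome-unique, `"mid"` is intermediate.
#' Per-genome size factors are lognormal with coefficient of variation
#' `genome_size_cv` (scaling a genome's copy numbers changes its size but
#' not its cosine direction).
#'
#' @param otu_ids genome identifiers.
#' @param n_functions number of functions; for `"low"` redundancy at least
#'   `length(otu_ids)` so every genome has a unique function.
#' @param redundancy `"low"`, `"mid"` or `"high"`.
#' @param genome_size_cv lognormal CV of genome size factors (default 0.3).
#' @param identical if TRUE all genomes share one copy vector (zero
#'   functional dissimilarity by construction).
#' @param seed integer seed.
#' @return list with `funcs` (OTUs x functions copy-number matrix) and
#'   `ground_truth` (redundancy level, carrier counts).
#' @export
simulate_genome_functions <- function(otu_ids, n_functions = 50,
                                      redundancy = c("low", "mid", "high"),
                                      genome_size_cv = 0.3,
                                      identical = FALSE, seed = 1) {
  redundancy <- match.arg(redundancy)
  n <- length(otu_ids)
  if (n < 1 || n_functions < 1) stop("need >= 1 genome and >= 1 function")
  set.seed(seed)
  fids <- sprintf("K%05d", seq_len(n_functions))
  if (identical) {
    v <- 1 + stats::rpois(n_functions, 1)
    funcs <- matrix(rep(v, each = n), n, n_functions,
                    dimnames = list(otu_ids, fids))
    return(list(funcs = funcs,
                ground_truth = list(redundancy = "identical",
                                    carriers = rep(n, n_functions))))
  }
  carry <- matrix(FALSE, n, n_functions)
  if (redundancy == "low") {
    if (n_functions < n)
      stop("low redundancy needs n_functions >= number of genomes")
    # one unique function per genome, remaining functions single-carrier
    carry[cbind(seq_len(n), seq_len(n))] <- TRUE
    if (n_functions > n)
      carry[cbind(sample.int(n, n_functions - n, replace = TRUE),
                  seq(n + 1, n_functions))] <- TRUE
  } else {
    pr <- if (redundancy == "high") 0.9 else 0.3
    carry <- matrix(stats::runif(n * n_functions) < pr, n, n_functions)
    empty_g <- which(rowSums(carry) == 0)
    for (g in empty_g) carry[g, sample.int(n_functions, 1)] <- TRUE
    empty_f <- which(colSums(carry) == 0)
    for (k in empty_f) carry[sample.int(n, 1), k] <- TRUE
  }
  copies <- matrix(1 + stats::rpois(n * n_functions, 0.5), n, n_functions)
  funcs <- carry * copies
  if (genome_size_cv > 0) {
    sdl <- sqrt(log(1 + genome_size_cv^2))
    size <- stats::rlnorm(n, -sdl^2 / 2, sdl)
    funcs <- funcs * size
  }
  dimnames(funcs) <- list(otu_ids, fids)
  list(funcs = funcs,
       ground_truth = list(redundancy = redundancy,
                           carriers = colSums(carry)))
}
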