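test_that("beta_mntd matches hand computations and the brute-force oracle", {
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(beta_mntd(c(A = 1), c(C = 1), tr4), 4)
  expect_equal(beta_mntd(c(A = 0.5, B = 0.5), c(A = 0.5, B = 0.5), tr4), 0)
  p <- c(A = 0.25, B = 0.25, C = 0.25, D = 0.25)
  expect_equal(beta_mntd(p, p, tr4), 0)

  # exhaustive support/abundance grids on 4- and 5-tip trees
  trees <- list(tr4,
                ape::read.tree(text = "(((A:1,B:2):1,(C:1,D:1):2):1,E:3);"))
  weights <- list(c(1), c(1, 1), c(2, 1), c(1, 1, 1), c(3, 1, 2))
  for (tr in trees) {
    D <- ape::cophenetic.phylo(tr)
    tips <- tr$tip.label
    for (w1 in weights) for (w2 in weights) {
      if (length(w1) > length(tips) || length(w2) > length(tips)) next
      s1 <- utils::combn(tips, length(w1))
      s2 <- utils::combn(tips, length(w2))
      for (i in seq_len(ncol(s1))) for (j in seq_len(ncol(s2))) {
        p1 <- stats::setNames(numeric(length(tips)), tips)
        p2 <- p1
        p1[s1[, i]] <- w1 / sum(w1)
        p2[s2[, j]] <- w2 / sum(w2)
        expect_equal(beta_mntd(p1, p2, tr), naive_bmntd(p1, p2, D),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("beta_mntd agrees with picante::comdistnt on sparse communities", {
  skip_if_not_installed("picante")
  set.seed(11)
  tr <- ape::rtree(15)
  m <- matrix(0, 2, 15, dimnames = list(c("s1", "s2"), tr$tip.label))
  m[1, sample(15, 6)] <- stats::rpois(6, 10) + 1
  m[2, sample(15, 5)] <- stats::rpois(5, 10) + 1
  rel <- to_relative(m)
  ours <- beta_mntd(rel[1, ], rel[2, ], tr)
  ref <- as.numeric(picante::comdistnt(m, ape::cophenetic.phylo(tr),
                                       abundance.weighted = TRUE))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("beta_nti with the exhaustive null equals the enumeration oracle
           and flags degenerate phylogenies", {
  tr4 <- ape::read.tree(text = "((A:1,B:3):2,(C:1,D:2):1);")
  set.seed(2)
  for (r in 1:5) {
    p1 <- stats::setNames(stats::runif(4) * (stats::runif(4) < 0.8), tr4$tip.label)
    p2 <- stats::setNames(stats::runif(4) * (stats::runif(4) < 0.8), tr4$tip.label)
    if (sum(p1) == 0) p1[1] <- 1
    if (sum(p2) == 0) p2[4] <- 1
    p1 <- p1 / sum(p1); p2 <- p2 / sum(p2)
    expect_equal(beta_nti(p1, p2, tr4, null = "exhaustive"),
                 naive_bnti_exhaustive(p1, p2, tr4), tolerance = 1e-10)
  }
  star <- suppressWarnings(prepare_tree(
    ape::read.tree(text = "(A:1,B:1,C:1,D:1);")))
  expect_warning(z <- beta_nti(c(A = 0.6, B = 0.4), c(C = 1), star,
                               null = "exhaustive"), "degenerate")
  expect_true(is.na(z))
})

test_that("RC_bray respects its bounds and boundary identities", {
  # table with strongly shared common OTUs plus two disjoint rare samples
  # rich enough (25 + 25 of 60) that null pairs always overlap, so the
  # observed complete turnover exceeds every null
  set.seed(4)
  n_otu <- 60
  common <- t(sapply(1:10, function(i)
    as.integer(stats::rmultinom(1, 1000, c(rep(0.15, 5), rep(0.25 / 55, 55))))))
  x <- integer(n_otu); x[6:30] <- 40L   # disjoint from y
  y <- integer(n_otu); y[31:55] <- 40L
  tab <- rbind(common, x, y)
  rownames(tab) <- c(paste0("c", 1:10), "x", "y")
  colnames(tab) <- paste0("o", 1:n_otu)

  # identical samples made of the commonest taxa: below nearly every null
  rc_lo <- raup_crick_bray("c1", "c1", tab, n_iter = 199, seed = 1)
  expect_lte(rc_lo, -0.95)
  # disjoint rare samples: observed dissimilarity above the nulls
  rc_hi <- raup_crick_bray("x", "y", tab, n_iter = 199, seed = 2)
  expect_equal(rc_hi, 1)
  # bounds on arbitrary pairs
  set.seed(9)
  for (r in 1:5) {
    pair <- sample(rownames(tab), 2)
    rc <- raup_crick_bray(pair[1], pair[2], tab, n_iter = 49, seed = r)
    expect_true(rc >= -1 && rc <= 1)
  }
  expect_error(raup_crick_bray("x", "y", tab, n_iter = 0), "n_iter")
})

test_that("classify_pair reproduces the five-way decision tree", {
  expect_equal(classify_pair(2.5), "variable_selection")
  expect_equal(classify_pair(-2.5), "homogeneous_selection")
  expect_equal(classify_pair(0.3, 0.99), "dispersal_limitation")
  expect_equal(classify_pair(0.3, -0.99), "homogenizing_dispersal")
  expect_equal(classify_pair(0.3, 0), "undominated")
  expect_equal(classify_pair(2, 0.96), "dispersal_limitation") # boundary: not > 2
  expect_error(classify_pair(0.3), "rc_bray required")
  expect_error(classify_pair(NaN, 0), "finite")
})

test_that("process percentages count correctly and always sum to 100", {
  res <- process_percentages(
    c("dispersal_limitation", "dispersal_limitation", "undominated",
      "variable_selection"), rep("g", 4))
  expect_equal(res$dispersal_limitation, 50)
  expect_equal(res$undominated, 25)
  expect_equal(res$variable_selection, 25)
  expect_equal(res$homogeneous_selection, 0)
  res2 <- process_percentages(rep("undominated", 7), rep("g", 7))
  expect_equal(res2$undominated, 100)
  set.seed(5)
  labs <- sample(c("variable_selection", "homogeneous_selection",
                   "dispersal_limitation", "homogenizing_dispersal",
                   "undominated"), 40, replace = TRUE)
  grp <- sample(c("a", "b"), 40, replace = TRUE)
  res3 <- process_percentages(labs, grp)
  sums <- rowSums(res3[, c("variable_selection", "homogeneous_selection",
                           "dispersal_limitation", "homogenizing_dispersal",
                           "undominated")])
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_error(process_percentages(character(0), character(0)), "no classified")
})

test_that("the qpe wrapper classifies within- and between-group pairs", {
  tr <- simulate_tree(50, seed = 41)
  meta <- simulate_metacommunity(tr, seed = 41)
  sim <- simulate_community_series(tr, meta, sim_config(
    seed = 42, groups = c("A", "B"), n_timepoints = 1, n_samples = 3,
    regime = "neutral", migration = 0.8, library_size = 250))
  q <- qpe(sim$table, tr, sim$metadata$group, n_iter = 49, seed = 1)
  expect_s3_class(q, "qpe")
  expect_equal(nrow(q$pairs), 6) # 3 within A + 3 within B
  classified <- q$pairs$process[!is.na(q$pairs$beta_nti)]
  expect_true(all(classified %in% c(
    "variable_selection", "homogeneous_selection", "dispersal_limitation",
    "homogenizing_dispersal", "undominated")))
  qb <- suppressWarnings(qpe(sim$table, tr, sim$metadata$group, n_iter = 49,
                             seed = 1, pairs = "between"))
  expect_equal(nrow(qb$pairs), 9)
  expect_equal(unique(qb$pairs$group), "A:B")
})
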