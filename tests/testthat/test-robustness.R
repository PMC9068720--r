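test_that("community function profiles are abundance-weighted copy sums", {
  funcs <- matrix(c(1, 0, 2,
                    0, 3, 1), 2, 3, byrow = TRUE,
                  dimnames = list(c("t1", "t2"), c("K1", "K2", "K3")))
  expect_equal(unname(community_function_profile(c(t1 = 1), funcs)),
               c(1, 0, 2))
  expect_equal(unname(community_function_profile(c(t1 = 0.5, t2 = 0.5), funcs)),
               c(0.5, 1.5, 1.5))
  set.seed(3)
  F5 <- matrix(stats::runif(20), 5, 4,
               dimnames = list(paste0("t", 1:5), paste0("K", 1:4)))
  p <- stats::runif(5); p <- p / sum(p); names(p) <- rownames(F5)
  expect_equal(unname(community_function_profile(p, F5)),
               unname(as.vector(p %*% F5)), tolerance = 1e-12)
  expect_error(community_function_profile(c(zz = 1), F5), "no overlap")
})

test_that("perturbations remove taxa and renormalize", {
  p <- c(a = 0.5, b = 0.5)
  perts <- perturb_sample(p, n_perturb = 10, seed = 1)
  for (q in perts) {
    expect_equal(sum(q), 1)
    expect_equal(sum(q > 0), 1) # k can only be 1 of S-1 = 1
  }
  set.seed(2)
  p8 <- stats::runif(8); p8 <- p8 / sum(p8); names(p8) <- letters[1:8]
  perts8 <- perturb_sample(p8, n_perturb = 50, seed = 3)
  for (q in perts8) {
    expect_lt(abs(sum(q) - 1), 1e-12)
    expect_gte(sum(q > 0), 1)
    expect_lt(sum(q > 0), 8)
  }
  expect_error(perturb_sample(c(a = 1), 10), "richness")
  # determinism
  expect_identical(perturb_sample(p8, 5, seed = 9),
                   perturb_sample(p8, 5, seed = 9))
})

test_that("functional shift is cosine dissimilarity with scale invariance", {
  expect_equal(functional_shift(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(functional_shift(c(1, 0), c(0, 2)), 1)
  f1 <- c(1, 2, 0.5); f2 <- c(0.3, 1, 2)
  expect_equal(functional_shift(f1, f2), functional_shift(5 * f1, f2))
  expect_equal(functional_shift(f1, f2), functional_shift(f1, 0.1 * f2))
  expect_true(is.na(functional_shift(c(0, 0), c(1, 1))))
})

test_that("taxonomic shift is weighted UniFrac and orders removals by
           phylogenetic distance", {
  tr <- ape::read.tree(text = "((A:1,B:1):3,(C:1,D:1):3);")
  p <- c(A = 0.4, B = 0.2, C = 0.2, D = 0.2)
  expect_equal(taxonomic_shift(p, p, tr), 0)
  expect_equal(taxonomic_shift(p, c(A = 1, B = 0, C = 0, D = 0), tr),
               generalized_unifrac(p, c(A = 1), tr, alpha = 1))
  # removing a distant-subtree taxon shifts more than a close relative
  drop_b <- p; drop_b["B"] <- 0; drop_b <- drop_b / sum(drop_b)
  drop_c <- p; drop_c["C"] <- 0; drop_c <- drop_c / sum(drop_c)
  expect_gt(taxonomic_shift(p, drop_c, tr), taxonomic_shift(p, drop_b, tr))
})

test_that("the attenuation/buffering regression recovers closed-form
           relationships exactly", {
  t <- seq(0.02, 0.9, length.out = 40)
  fit1 <- fit_robustness(t, t)
  expect_equal(fit1$a, 0, tolerance = 1e-12)
  expect_equal(fit1$b, 1, tolerance = 1e-12)
  fit2 <- fit_robustness(t, t^2 * exp(-3))
  expect_equal(fit2$a, 3, tolerance = 1e-10)
  expect_equal(fit2$b, 2, tolerance = 1e-10)
  expect_false(fit2$degenerate)
  # majority-zero functional shifts: censored-high attenuation
  fz <- c(rep(0, 30), t[1:10])
  fit3 <- fit_robustness(t, fz)
  expect_true(fit3$degenerate)
  expect_identical(fit3$a, Inf)
  expect_error(fit_robustness(t[1:4], t[1:4]), ">= 5")
})

test_that("gene distribution features match brute-force loops", {
  funcs <- matrix(c(2, 1, 0, 0, 0, 1,
                    0, 1, 3, 0, 0, 0,
                    0, 0, 0, 2, 0, 1,
                    1, 0, 0, 0, 4, 0), 4, 6, byrow = TRUE,
                  dimnames = list(paste0("t", 1:4), paste0("K", 1:6)))
  p <- c(t1 = 0.4, t2 = 0.3, t3 = 0.2, t4 = 0.1)
  g <- gene_distribution_features(p, funcs)
  sizes <- rowSums(funcs)
  expect_equal(unname(g["avg_genome_size"]), sum(p * sizes))
  expect_equal(unname(g["genome_size_variability"]),
               sqrt(sum(p * (sizes - sum(p * sizes))^2)))
  # pairwise cosine dissimilarity, abundance-pair-weighted
  num <- 0; den <- 0
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    cs <- sum(funcs[i, ] * funcs[j, ]) /
      (sqrt(sum(funcs[i, ]^2)) * sqrt(sum(funcs[j, ]^2)))
    num <- num + p[i] * p[j] * (1 - cs)
    den <- den + p[i] * p[j]
  }
  expect_equal(unname(g["avg_functional_dissimilarity"]), unname(num / den),
               tolerance = 1e-12)
  # redundancy: community-abundance-weighted carrier counts
  profile <- as.vector(p %*% funcs)
  carriers <- colSums(funcs > 0)
  expect_equal(unname(g["avg_functional_redundancy"]),
               sum(profile * carriers) / sum(profile), tolerance = 1e-12)
  # unique functions: K1 (t1,t4 -> 2 carriers? no: K1 carried by t1,t4) ...
  uniq <- which(carriers == 1)
  expect_equal(unname(g["unique_function_abundance"]),
               sum(profile[uniq]) / sum(profile), tolerance = 1e-12)
})

test_that("gene distribution features have the documented degenerate values", {
  ids <- paste0("t", 1:4)
  idm <- simulate_genome_functions(ids, 10, identical = TRUE, seed = 1)$funcs
  p <- stats::setNames(c(0.4, 0.3, 0.2, 0.1), ids)
  g <- gene_distribution_features(p, idm)
  expect_equal(unname(g["genome_size_variability"]), 0)
  expect_equal(unname(g["avg_functional_dissimilarity"]), 0)
  expect_equal(unname(g["unique_function_abundance"]), 0)
  # disjoint single-function genomes: redundancy 1, all functions unique
  dj <- diag(4); dimnames(dj) <- list(ids, paste0("K", 1:4))
  g2 <- gene_distribution_features(p, dj)
  expect_equal(unname(g2["avg_functional_redundancy"]), 1)
  expect_equal(unname(g2["unique_function_abundance"]), 1)
  expect_equal(unname(g2["avg_functional_dissimilarity"]), 1)
  # single-taxon community: dissimilarity undefined
  g3 <- gene_distribution_features(c(t1 = 1), dj)
  expect_true(is.na(g3["avg_functional_dissimilarity"]))
})

test_that("per-category fits reuse one perturbation set and the all-function
           category equals the global fit", {
  tr <- simulate_tree(12, seed = 61)
  funcs <- simulate_genome_functions(tr$tip.label, 20, "mid", seed = 62)$funcs
  p <- stats::setNames(rep(1 / 12, 12), tr$tip.label)
  cmap <- stats::setNames(rep("all", 20), colnames(funcs))
  bycat <- robustness_by_category(p, tr, funcs, cmap, n_perturb = 40,
                                  seed = 77)
  # reproduce manually with the same perturbation seed
  perts <- perturb_sample(p, 40, seed = 77)
  tsh <- vapply(perts, function(q) taxonomic_shift(p, q, tr), numeric(1))
  F0 <- community_function_profile(p, funcs)
  fsh <- vapply(perts, function(q)
    functional_shift(F0, community_function_profile(q, funcs)), numeric(1))
  ref <- fit_robustness(tsh, fsh)
  expect_equal(bycat$a, ref$a, tolerance = 1e-12)
  expect_equal(bycat$b, ref$b, tolerance = 1e-12)
  expect_error(robustness_by_category(p, tr, funcs,
                                      c(NOPE = "x"), 10), "no functions")
})

test_that("robustness profiles are seeded-reproducible and flag identical-
           genome communities as degenerate", {
  tr <- simulate_tree(15, seed = 71)
  tab <- random_table(4, 15, seed = 72, sparsity = 0.2)
  colnames(tab) <- tr$tip.label
  idm <- simulate_genome_functions(tr$tip.label, 12, identical = TRUE,
                                   seed = 73)$funcs
  r1 <- robustness(tab, tr, idm, n_perturb = 30, seed = 5)
  expect_true(all(r1$samples$degenerate))
  expect_true(all(is.infinite(r1$samples$a)))

  funcs <- simulate_genome_functions(tr$tip.label, 25, "mid", seed = 74)$funcs
  r2 <- robustness(tab, tr, funcs, n_perturb = 30, seed = 6)
  r3 <- robustness(tab, tr, funcs, n_perturb = 30, seed = 6)
  expect_identical(r2$samples, r3$samples)
  expect_true(all(is.finite(r2$samples$a)))
})

test_that("GDF ordination preserves structure", {
  X <- rbind(matrix(rep(c(1, 2, 3), each = 4), 4),
             matrix(rep(c(5, 1, 0), each = 4), 4))
  rownames(X) <- paste0("s", 1:8)
  colnames(X) <- c("f1", "f2", "f3")
  ord <- gdf_ordination(X, k = 2)
  expect_gt(ord$percent_variance[1], 99.9)
  expect_lt(diff(range(ord$points[1:4, 1])), 1e-9) # cluster coincides
  set.seed(8)
  Y <- matrix(stats::rnorm(30), 6, 5,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:5)))
  ord2 <- gdf_ordination(Y, k = 5)
  d_embed <- stats::dist(ord2$points)
  d_raw <- stats::dist(scale(Y))
  expect_equal(as.numeric(d_embed), as.numeric(d_raw), tolerance = 1e-9)
  Yc <- cbind(Y, const = 1)
  expect_warning(gdf_ordination(Yc), "constant")
})
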