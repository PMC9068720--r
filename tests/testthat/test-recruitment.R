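test_that("faith_pd matches hand computations and is monotone under
           inclusion", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(faith_pd("A", tr), 2)
  expect_equal(faith_pd(c("A", "B", "C"), tr), sum(tr$edge.length))
  expect_equal(faith_pd(c("A", "B"), tr), 3)
  pd_ab <- faith_pd(c("A", "B"), tr)
  expect_gte(faith_pd(c("A", "B", "C"), tr), pd_ab)
  expect_error(faith_pd(character(0), tr), "empty")
  expect_error(faith_pd("Z", tr), "not in tree")
})

test_that("faith_pd agrees with picante::pd including the root", {
  skip_if_not_installed("picante")
  set.seed(19)
  tr <- ape::rtree(20)
  for (r in 1:5) {
    s <- sample(tr$tip.label, sample(2:10, 1))
    m <- matrix(as.integer(tr$tip.label %in% s), 1,
                dimnames = list("x", tr$tip.label))
    ref <- picante::pd(m, tr, include.root = TRUE)$PD
    expect_equal(faith_pd(s, tr), ref, tolerance = 1e-10)
  }
})

test_that("detection_series finds first detections with pooling within
           time points", {
  tab <- rbind(
    s1 = c(A = 5L, B = 2L, C = 0L, D = 0L),
    s2 = c(A = 1L, B = 0L, C = 0L, D = 0L),
    s3 = c(A = 4L, B = 1L, C = 3L, D = 0L),
    s4 = c(A = 0L, B = 2L, C = 1L, D = 0L))
  md <- data.frame(sample_id = paste0("s", 1:4),
                   time_point = factor(c("t1", "t1", "t2", "t2"),
                                       ordered = TRUE),
                   group = "g")
  ds <- detection_series(tab, md, "g")
  expect_equal(sort(ds$new$t1), c("A", "B"))
  expect_equal(ds$new$t2, "C") # A and B already seen; D never detected
  # higher detection threshold changes what counts as detected
  ds2 <- detection_series(tab, md, "g", presence_min_count = 3)
  expect_equal(sort(ds2$new$t1), c("A"))
  expect_equal(sort(ds2$new$t2), c("A", "C")[2]) # A at t2 has 4 >= 3 but seen
  expect_error(detection_series(tab, md, "nope"), "no samples")
})

test_that("dispersion fit recovers sign and is exactly invariant to branch
           rescaling", {
  tr <- simulate_tree(60, seed = 51)
  sim <- simulate_recruitment_series(tr, 1.5, 6, 6, seed = 52)
  fit <- fit_dispersion(sim$series, tr, n_rep = 80, n_boot = 59, seed = 53,
                        D_grid = seq(-3, 3, 0.5))
  expect_s3_class(fit, "recruitment_fit")
  expect_gt(fit$D_hat, 0)
  expect_equal(unname(coef(fit)), fit$D_hat)
  ci <- confint(fit)
  expect_lte(ci[1], fit$D_hat)
  expect_gte(ci[2], fit$D_hat)

  tr10 <- tr
  tr10$edge.length <- tr10$edge.length * 10
  fit10 <- fit_dispersion(sim$series, tr10, n_rep = 80, n_boot = 59,
                          seed = 53, D_grid = seq(-3, 3, 0.5))
  expect_equal(fit10$D_hat, fit$D_hat, tolerance = 1e-6)
  expect_equal(fit10$ci95, fit$ci95, tolerance = 1e-6)

  simn <- simulate_recruitment_series(tr, -1.5, 6, 6, seed = 52)
  fitn <- fit_dispersion(simn$series, tr, n_rep = 80, n_boot = 59, seed = 53,
                         D_grid = seq(-3, 3, 0.5))
  expect_lt(fitn$D_hat, 0)
})

test_that("a star phylogeny leaves dispersion unidentifiable", {
  star <- suppressWarnings(prepare_tree(ape::read.tree(
    text = paste0("(", paste0("t", 1:20, ":1", collapse = ","), ");"))))
  series <- list(t1 = paste0("t", 1:4), t2 = paste0("t", 5:10),
                 t3 = paste0("t", 11:16), t4 = paste0("t", 17:20))
  expect_warning(fit <- fit_dispersion(series, star, n_rep = 30, n_boot = 19,
                                       seed = 1, D_grid = seq(-2, 2, 1)),
                 "unidentifiable")
  expect_true(fit$flags$unidentifiable)
  expect_true(is.na(fit$D_hat))
})

test_that("expected early-PD accumulation increases with dispersion", {
  tr <- simulate_tree(30, seed = 81)
  early_pd_frac <- function(D_true) {
    mean(vapply(1:40, function(s) {
      sim <- simulate_recruitment_series(tr, D_true, 5, 2, seed = s)
      cum <- unique(unlist(sim$series$new[1:2]))
      faith_pd(cum, tr) / faith_pd(tr$tip.label, tr)
    }, numeric(1)))
  }
  f <- vapply(c(-2, 0, 2), early_pd_frac, numeric(1))
  expect_lt(f[1], f[2])
  expect_lt(f[2], f[3])
})
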