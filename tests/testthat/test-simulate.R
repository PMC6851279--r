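# Synthetic-data generators: determinism, noise calibration, planted truth.

test_that("parameter sampling is deterministic and respects its ranges", {
  expect_identical(sample_params(0), setNames(list(), character(0)))
  p1 <- sample_params(5, seed = 2)
  p2 <- sample_params(5, seed = 2)
  expect_identical(p1, p2)
  tab <- params_table(sample_params(50, seed = 3))
  expect_true(all(tab$eta >= 1 & tab$eta <= 1e3))
  expect_true(all(tab$n >= 0.5 & tab$n <= 6))
  expect_true(all(tab$Km_cAMP >= 0.05 & tab$Km_cAMP <= 100))
})

test_that("the a-eta copula induces a negative correlation", {
  tab <- params_table(sample_params(200, seed = 4, correlate_a_eta = TRUE))
  expect_lt(cor(log10(tab$a), log10(tab$eta)), -0.4)
  tab0 <- params_table(sample_params(200, seed = 4, correlate_a_eta = FALSE))
  expect_lt(abs(cor(log10(tab0$a), log10(tab0$eta))), 0.25)
})

test_that("landscape noise has the configured multiplicative CV", {
  p <- demo_params()
  clean <- simulate_landscape(p, noise_cv = 0, seed = 5)
  expect_equal(clean$landscape$values, clean$truth$values)
  # empirical CV of one cell across many replicate draws
  sim <- simulate_landscape(p, noise_cv = 0.1, n_replicates = 1000, seed = 6)
  cell <- sim$replicates[4, 5, ]
  truth <- sim$truth$values[4, 5]
  expect_equal(sd(cell) / mean(cell), 0.1, tolerance = 0.05)
  # averaging replicates shrinks the cell-level sd ~ 1/sqrt(n)
  many <- vapply(1:200, function(i)
    simulate_landscape(p, noise_cv = 0.1, n_replicates = 4,
                       seed = 100 + i)$landscape$values[4, 5], numeric(1))
  expect_equal(sd(many) / truth, 0.1 / sqrt(4), tolerance = 0.3)
})

test_that("tree and trait simulation have the requested signal structure", {
  sim <- simulate_tree_and_traits(24, lambda_true = 0, seed = 7,
                                  n_traits = 50)
  # unit depth scaling
  depths <- ape::node.depth.edgelength(sim$tree)[1:24]
  expect_equal(max(depths), 1)
  # lambda = 0 -> traits iid: cross-tip sample covariances centred on 0
  S <- cov(t(sim$traits))
  off <- S[upper.tri(S)]
  expect_lt(abs(mean(off)), 0.1)
  # lambda = 1 -> trait covariance tracks the tree covariance
  sim1 <- simulate_tree_and_traits(24, lambda_true = 1, seed = 8,
                                   n_traits = 200)
  S1 <- cov(t(sim1$traits))
  C <- phylo_covariance(sim1$tree, 1)
  expect_gt(cor(S1[upper.tri(S1)], C[upper.tri(C)]), 0.5)
  # newick round trip preserves patristic distances
  tmp <- tempfile(fileext = ".nwk")
  ape::write.tree(sim$tree, tmp)
  back <- ape::read.tree(tmp)
  d1 <- ape::cophenetic.phylo(sim$tree)
  d2 <- ape::cophenetic.phylo(back)[rownames(d1), colnames(d1)]
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("SNP simulation plants detectable signal and stays polymorphic", {
  tab <- params_table(sample_params(20, seed = 9))
  sm <- simulate_snp_matrix(tab, n_sites = 120, n_causal = 2, n_linked = 3,
                            effect_size = 3, seed = 10)
  A <- sm$snps$alleles
  expect_true(all(apply(A, 2, function(cl) length(unique(cl)) == 2)))
  expect_identical(nrow(sm$registry), 2L * (1L + 3L))
  # linked copies are exact duplicates of their causal column
  for (g in unique(sm$registry$group)) {
    sites <- sm$registry$site[sm$registry$group == g]
    for (s in sites[-1]) expect_identical(A[, s], A[, sites[1]])
  }
  # effect_size = 0 -> no registry entries
  sm0 <- simulate_snp_matrix(tab, n_sites = 50, n_causal = 1,
                             effect_size = 0, seed = 11)
  expect_identical(nrow(sm0$registry), 0L)
  expect_identical(simulate_snp_matrix(tab, n_sites = 50, seed = 12)$snps,
                   simulate_snp_matrix(tab, n_sites = 50, seed = 12)$snps)
})

test_that("growth panel lag model has the configured directions", {
  tab <- params_table(sample_params(18, seed = 13))
  gp <- simulate_growth_panel(tab, beta0 = 400, beta_a = -60, beta_eta = 60,
                              sigma = 0, seed = 14)
  expect_identical(length(gp$curves), 18L * 3L)
  za <- as.numeric(scale(log10(tab$a)))
  ze <- as.numeric(scale(log10(tab$eta)))
  expect_equal(unname(gp$true_lags),
               pmax(400 - 60 * za + 60 * ze, 0), tolerance = 1e-10)
  gp2 <- simulate_growth_panel(tab, beta0 = 400, beta_a = -60, beta_eta = 60,
                               sigma = 0, seed = 14)
  expect_identical(gp$true_lags, gp2$true_lags)
  expect_equal(gp$curves[[5]]$od, gp2$curves[[5]]$od)
})

test_that("a full synthetic study is reproducible end-to-end", {
  cfg <- sim_config(seed = 77, n_strains = 6, n_sites = 40,
                    grid = small_grid())
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$params_tab, s2$params_tab)
  expect_identical(s1$landscapes[[3]]$values, s2$landscapes[[3]]$values)
  expect_identical(s1$true_lags, s2$true_lags)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})
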