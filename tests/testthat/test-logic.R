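# Logic phenotyping, landscape distance metric and clustering.

test_that("corner landscape yields the hand-computed logic statistics", {
  ls <- corner_landscape(ll = 1, hl = 57, lh = 21, hh = 100)
  lp <- logic_phenotype(ls)
  expect_equal(lp$f_iptg, 0.57)
  expect_equal(lp$f_camp, 0.21)
  expect_equal(lp$synergy, 1 - (0.57 + 0.21 - 0.57 * 0.21))  # 0.3397
  expect_equal(lp$synergy, 0.3397)
  expect_equal(lp$pi1, log10(1) / 2)
  expect_equal(lp$pi2, log10(57) / 2)
  expect_equal(lp$pi3, log10(21) / 2)
})

test_that("constant landscape gives the neutral phenotype", {
  ls <- corner_landscape(5, 5, 5, 5)
  lp <- logic_phenotype(ls)
  expect_equal(unlist(lp[c("pi1", "pi2", "pi3")]), c(pi1 = 1, pi2 = 1, pi3 = 1))
  expect_equal(lp$f_iptg, 1)
  expect_equal(lp$f_camp, 1)
  expect_equal(lp$synergy, 0)
})

test_that("ideal AND landscape maps to low pi and high synergy", {
  ls <- corner_landscape(1, 1, 1, 100)
  lp <- logic_phenotype(ls)
  expect_equal(unlist(lp[c("pi1", "pi2", "pi3")], use.names = FALSE),
               c(0, 0, 0))
  expect_equal(lp$synergy, 1 - (0.01 + 0.01 - 1e-4))
  expect_gt(lp$synergy, 0.9)
  expect_error(logic_phenotype(corner_landscape(0, 0, 0, 0)), "degenerate")
})

test_that("model-generated extremes reproduce AND and IPTG-only profiles", {
  base <- list(alpha = 1000, gamma = 0.01, n = 2, m = 2, Km_cAMP = 5,
               Km_IPTG = 20)
  # strong repression (large b) plus polymerase recruitment that requires
  # cAMP-CRP (tiny a, large eta*d*a): both inducers needed -> AND
  and_p <- do.call(regulatory_params,
                   c(base, list(a = 0.001, b = 1000, d = 1, eta = 1000)))
  lp_and <- logic_phenotype(predict_landscape(default_grid(), and_p))
  expect_true(all(unlist(lp_and[c("pi1", "pi2", "pi3")]) < 0.25))
  # strong repression but no CRP coupling (d = 0): IPTG alone suffices
  iptg_p <- do.call(regulatory_params,
                    c(base, list(a = 1, b = 1000, d = 0, eta = 1)))
  lp_i <- logic_phenotype(predict_landscape(default_grid(), iptg_p))
  expect_gt(lp_i$pi2, 0.95)
  expect_lt(lp_i$pi1, 0.5)
})

test_that("landscape distance is a metric and matches hand computation", {
  g <- inducer_grid(c(0, 40), c(0, 200))
  mk <- function(v, id) expression_landscape(id, g, matrix(v, 2, 2) * 50)
  # normalised corner matrices [[0,0],[0,1]] vs [[0,0],[1,1]] differ in one
  # cell -> distance 1 (values scaled by 50, normalisation divides it out)
  l1 <- mk(c(0, 0, 0, 1), "a")
  l2 <- mk(c(0, 1, 0, 1), "b")
  expect_equal(landscape_distance(l1, l2), 1.0)
  set.seed(31)
  for (i in 1:10) {
    ls <- lapply(1:3, function(k)
      expression_landscape(paste0("s", k), g, matrix(runif(4, 0, 100), 2)))
    d12 <- landscape_distance(ls[[1]], ls[[2]])
    d13 <- landscape_distance(ls[[1]], ls[[3]])
    d23 <- landscape_distance(ls[[2]], ls[[3]])
    expect_gte(d12, 0)
    expect_equal(d12, landscape_distance(ls[[2]], ls[[1]]))
    expect_equal(landscape_distance(ls[[1]], ls[[1]]), 0)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
  expect_error(
    landscape_distance(l1, expression_landscape("c", small_grid(),
                                                matrix(1, 4, 4))),
    "grids")
})

test_that("clustering merges the closest landscapes first", {
  donor <- demo_params()
  recipient <- unclass(donor)
  recipient[c("a", "eta", "b")] <- c(2, 2, 500)
  hybrid <- recipient
  hybrid["Km_IPTG"] <- recipient["Km_IPTG"] * 1.2
  g <- default_grid()
  ls <- list(predict_landscape(g, donor, "donor"),
             predict_landscape(g, recipient, "recipient"),
             predict_landscape(g, hybrid, "hybrid"))
  hc <- cluster_landscapes(ls)
  # oracle: the pair at minimal pairwise distance must merge first
  D <- landscape_dist_matrix(ls)
  pair <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
  expect_setequal(hc$labels[-hc$merge[1, ]], rownames(D)[pair])
  expect_setequal(rownames(D)[pair], c("recipient", "hybrid"))
  expect_true(all(diff(hc$height) >= -1e-12))

  # identical pair merges at height zero
  ls2 <- list(ls[[1]], predict_landscape(g, donor, "donor2"), ls[[2]])
  hc2 <- cluster_landscapes(ls2)
  expect_equal(hc2$height[1], 0)
  expect_error(cluster_landscapes(ls[1]), "two")
})
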