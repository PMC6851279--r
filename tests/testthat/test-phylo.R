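# Phylogenetic covariance, Pagel's lambda, Mantel test, PD bootstrap.

test_that("lambda-transformed covariance has the hand-computed structure", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C0 <- phylo_covariance(tree, 0)
  expect_true(all(C0[upper.tri(C0)] == 0))
  expect_equal(diag(C0), c(A = 2, B = 2, C = 2))
  C1 <- phylo_covariance(tree, 1)
  expect_equal(C1["A", "B"], 1)
  expect_equal(C1["A", "C"], 0)
  Ch <- phylo_covariance(tree, 0.4)
  expect_equal(Ch["A", "B"], 0.4)          # off-diagonals linear in lambda
  expect_equal(diag(Ch), diag(C1))
  expect_error(phylo_covariance(tree, 1.5), "lambda")
})

test_that("lambda estimate maximises the profile likelihood over a grid", {
  sim <- simulate_tree_and_traits(32, lambda_true = 0.6, seed = 14)
  y <- setNames(sim$traits[, 1], rownames(sim$traits))
  res <- pagel_lambda_test(sim$tree, y)
  C <- ape::vcv.phylo(sim$tree)
  grid_ll <- vapply(seq(0, 1, length.out = 101), function(l) {
    Cl <- C * l; diag(Cl) <- diag(C)
    lacreg:::pagel_profile_ll(Cl, as.numeric(y[rownames(C)]))$ll
  }, numeric(1))
  expect_gte(res$loglik_ml, max(grid_ll) - 1e-6)
  expect_gte(res$loglik_ml, res$loglik_zero)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("the lambda = 0 limit reduces to ordinary mean and variance", {
  sim <- simulate_tree_and_traits(16, lambda_true = 0, seed = 15)
  y <- as.numeric(sim$traits[, 1])
  # equal root-to-tip depths make C(0) = depth * I, so the GLS profile at
  # lambda = 0 is the iid normal fit
  C0 <- phylo_covariance(sim$tree, 0)
  prof <- lacreg:::pagel_profile_ll(C0, y)
  expect_equal(prof$mu, mean(y), tolerance = 1e-10)
  expect_equal(prof$sigma2 * C0[1, 1], var(y) * (length(y) - 1) / length(y),
               tolerance = 1e-10)
})

test_that("lambda estimates agree with the reference implementation", {
  skip_if_not_installed("phytools")
  sim <- simulate_tree_and_traits(48, lambda_true = 0.7, seed = 16)
  y <- setNames(sim$traits[, 1], rownames(sim$traits))
  mine <- pagel_lambda_test(sim$tree, y)
  ref <- phytools::phylosig(sim$tree, y, method = "lambda", test = TRUE)
  expect_equal(mine$lambda, min(ref$lambda, 1), tolerance = 0.02)
  expect_equal(mine$loglik_zero, ref$logL0, tolerance = 1e-4)
  if (ref$lambda <= 1)
    expect_equal(mine$loglik_ml, ref$logL, tolerance = 1e-3)
})

test_that("star phylogenies are flagged as non-identifiable", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  y <- setNames(rnorm(5), star$tip.label)
  res <- pagel_lambda_test(star, y)
  expect_false(res$identifiable)
  expect_identical(res$p_value, 1)
})

test_that("degenerate traits and tiny overlaps are rejected", {
  sim <- simulate_tree_and_traits(8, seed = 18)
  expect_error(pagel_lambda_test(sim$tree,
                                 setNames(rep(1, 8), sim$tree$tip.label)),
               "constant")
  expect_error(pagel_lambda_test(sim$tree,
                                 setNames(rnorm(3), sim$tree$tip.label[1:3])),
               "4 tips")
  # unmatched tips are pruned with a message, not an error
  y <- setNames(rnorm(6), sim$tree$tip.label[1:6])
  expect_message(res <- pagel_lambda_test(sim$tree, y), "pruned")
  expect_identical(res$n_tips, 6L)
})

test_that("mantel test has its closed-form identity behaviour", {
  set.seed(19)
  D <- as.matrix(dist(matrix(rnorm(16), 8)))
  res <- mantel_test(D, D, n_perm = 999, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 1000)
  expect_error(mantel_test(D, matrix(0, 8, 8)), "constant")
  expect_error(mantel_test(D[1:5, 1:5], D), "size|objects")
})

test_that("mantel r equals the enumerated upper-triangle correlation", {
  set.seed(20)
  D1 <- as.matrix(dist(matrix(rnorm(10), 5)))
  D2 <- as.matrix(dist(matrix(rnorm(10), 5)))
  res <- mantel_test(D1, D2, n_perm = 99, seed = 2)
  # brute force over explicitly enumerated pairs i < j
  v1 <- c(); v2 <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    v1 <- c(v1, D1[i, j]); v2 <- c(v2, D2[i, j])
  }
  expect_equal(res$r, cor(v1, v2), tolerance = 1e-12)
  # reference implementation agrees on r and one-tailed p construction
  skip_if_not_installed("vegan")
  ref <- vegan::mantel(D1, D2, permutations = 999)
  expect_equal(res$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("mantel permutations are seed-reproducible", {
  set.seed(22)
  D1 <- as.matrix(dist(matrix(rnorm(24), 12)))
  D2 <- as.matrix(dist(matrix(rnorm(24), 12)))
  r1 <- mantel_test(D1, D2, n_perm = 199, seed = 7)
  r2 <- mantel_test(D1, D2, n_perm = 199, seed = 7)
  expect_identical(r1$p, r2$p)
  two <- mantel_test(D1, D2, n_perm = 199, tail = "two", seed = 7)
  expect_gte(two$p, 1 / 200)
})

test_that("phylogenetic diversity has its closed-form values and monotonicity", {
  set.seed(25)
  tree <- ape::rtree(12)
  expect_equal(phylo_diversity(tree, tree$tip.label),
               sum(tree$edge.length))
  pat <- ape::cophenetic.phylo(tree)
  expect_equal(phylo_diversity(tree, tree$tip.label[c(2, 9)]),
               pat[tree$tip.label[2], tree$tip.label[9]])
  # adding a tip never decreases pd
  sub <- tree$tip.label[1:3]
  for (tip in tree$tip.label[4:8]) {
    expect_gte(phylo_diversity(tree, c(sub, tip)),
               phylo_diversity(tree, sub) - 1e-12)
    sub <- c(sub, tip)
  }
})

test_that("pd bootstrap flags a clade-confined subset as unrepresentative", {
  sim <- simulate_tree_and_traits(32, seed = 26)
  tree <- sim$tree
  # pick the tips of one small clade (internal node with 4-8 descendants)
  internal <- (ape::Ntip(tree) + 2):max(tree$edge)
  sizes <- vapply(internal, function(nd)
    length(ape::extract.clade(tree, nd)$tip.label), integer(1))
  node <- internal[which(sizes >= 4 & sizes <= 8)[1]]
  clade_tips <- ape::extract.clade(tree, node)$tip.label
  res <- pd_representativeness(tree, clade_tips, n_draws = 500, seed = 3)
  expect_lt(res$p, 0.1)
  expect_error(pd_representativeness(tree, c("nope", clade_tips)), "nope")
  # random subsets are not flagged
  res2 <- pd_representativeness(tree, sample(tree$tip.label, 10),
                                n_draws = 500, seed = 4)
  expect_gt(res2$p, 0.05)
})
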