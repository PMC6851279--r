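# Mutual information, the max-statistic scan, PLS and correlations.

test_that("mutual information matches exhaustive contingency computation", {
  # enumeration oracle: explicit double loop over the joint table
  mi_oracle <- function(b, al) {
    n <- length(b)
    mi <- 0
    for (bb in unique(b)) for (aa in unique(al)) {
      pxy <- sum(b == bb & al == aa) / n
      if (pxy > 0)
        mi <- mi + pxy * log2(pxy / (sum(b == bb) / n * sum(al == aa) / n))
    }
    mi
  }
  set.seed(33)
  for (rep in 1:10) {
    x <- rnorm(12)
    al <- sample(c("a", "g", "-"), 12, replace = TRUE)
    if (length(unique(al)) < 2) next
    n_bins <- 2
    b <- ceiling(rank(x, ties.method = "first") * n_bins / 12)
    expect_equal(mutual_information(x, al, n_bins), mi_oracle(b, al),
                 tolerance = 1e-12)
  }
})

test_that("MI edge and invariance behaviour", {
  x <- c(rnorm(10), rnorm(10) + 50)
  al <- rep(c("a", "g"), each = 10)
  expect_equal(mutual_information(x, al, 2), 1.0)    # perfect split, 2 bins
  expect_warning(mi0 <- mutual_information(rep(3, 12),
                                           rep(c("a", "g"), 6), 2),
                 "constant")
  expect_identical(mi0, 0)
  # invariant to allele relabelling and monotone transforms of the parameter
  set.seed(34)
  x2 <- rnorm(16); al2 <- sample(c("t", "c"), 16, replace = TRUE)
  if (length(unique(al2)) == 2) {
    m1 <- mutual_information(x2, al2, 2)
    expect_equal(mutual_information(exp(3 * x2), al2, 2), m1)
    relab <- c(t = "x", c = "y")[al2]
    expect_equal(mutual_information(x2, relab, 2), m1)
  }
  expect_error(mutual_information(rnorm(12), rep("a", 12)), "monomorphic")
})

test_that("mi_scan flags a planted causal site and its linked copies", {
  set.seed(35)
  n <- 20
  tab <- data.frame(Km_IPTG = rnorm(n))
  rownames(tab) <- sprintf("S%02d", 1:n)
  sm <- simulate_snp_matrix(tab, n_sites = 300, n_causal = 1, n_linked = 4,
                            effect_size = 3, causal_param = "Km_IPTG",
                            seed = 36)
  scan <- mi_scan(tab, sm$snps, n_perm = 499, seed = 37)
  causal <- sm$registry$site[sm$registry$role == "causal"]
  linked <- sm$registry$site[sm$registry$role == "linked"]
  expect_true(scan$significant[1, causal])
  # linked exact copies carry identical MI and significance
  expect_true(all(scan$mi[1, linked] == scan$mi[1, causal]))
  expect_true(all(scan$significant[1, linked]))
  # corrected p monotone non-increasing in observed MI
  ord <- order(scan$mi[1, ])
  expect_true(all(diff(scan$p_corrected[1, ord]) <= 1e-12))
})

test_that("a single-site scan reduces to the single-test permutation p", {
  set.seed(38)
  n <- 16
  tab <- data.frame(a = rnorm(n)); rownames(tab) <- sprintf("S%02d", 1:n)
  al <- matrix(sample(c("a", "g"), n, replace = TRUE), ncol = 1,
               dimnames = list(rownames(tab), NULL))
  while (length(unique(al[, 1])) < 2)
    al[, 1] <- sample(c("a", "g"), n, replace = TRUE)
  snps <- snp_matrix(al, positions = 101L)
  scan <- mi_scan(tab, snps, n_perm = 499, seed = 39)
  # oracle: direct permutation test of the one site
  b <- ceiling(rank(tab$a, ties.method = "first") * 2 / n)
  mi_obs <- mutual_information(tab$a, al[, 1], 2)
  set.seed(39)
  perm <- replicate(499, mutual_information(tab$a[sample(n)], al[, 1], 2))
  expect_equal(unname(scan$p_corrected[1, 1]),
               (sum(perm >= mi_obs) + 1) / 500)
})

test_that("mi_scan is reproducible and controls the global-null FWER", {
  tab <- data.frame(g = rnorm(20)); rownames(tab) <- sprintf("S%02d", 1:20)
  sm <- simulate_snp_matrix(tab, n_sites = 100, n_causal = 0,
                            effect_size = 0, seed = 40)
  s1 <- mi_scan(tab, sm$snps, n_perm = 199, seed = 8)
  s2 <- mi_scan(tab, sm$snps, n_perm = 199, seed = 8)
  expect_identical(s1$p_corrected, s2$p_corrected)
  expect_true(all(s1$p_corrected > 0))
  # small FWER sanity: 40 null scans should flag rarely
  set.seed(41)
  hits <- vapply(1:40, function(i) {
    tabi <- data.frame(p = rnorm(20)); rownames(tabi) <- rownames(tab)
    smi <- simulate_snp_matrix(tabi, n_sites = 60, n_causal = 0,
                               effect_size = 0, seed = 500 + i)
    any(mi_scan(tabi, smi$snps, n_perm = 199, seed = i)$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.2)
})

test_that("PLS reproduces a single-predictor response exactly", {
  # orthogonal zero-mean design: with y equal to one column, the first
  # weight vector is that column's indicator, so component 1 explains all
  # of y and the variable's contribution is 100%
  X <- unclass(stats::poly(1:15, degree = 8))
  colnames(X) <- paste0("p", 1:8)
  y <- as.numeric(X[, 4])
  fit <- pls_fit(X, y, n_components = 1)
  expect_equal(unname(fit$y_variance_explained[1]), 100, tolerance = 1e-8)
  expect_gt(fit$contributions["p4", 1], 99.99)
})

test_that("full-rank PLS matches the OLS R-squared and sums contributions", {
  set.seed(44)
  X <- matrix(rnorm(200), 20) %*% diag(c(5, rep(1, 9)))  # correlated scales
  colnames(X) <- paste0("p", 1:10)
  y <- 2 * X[, 3] - X[, 7] + rnorm(20)
  fit <- pls_fit(X, y, n_components = 10)
  r2 <- 100 * summary(lm(y ~ X))$r.squared
  expect_equal(max(fit$cumulative_variance), r2, tolerance = 1e-8)
  expect_equal(unname(colSums(fit$contributions)),
               rep(100, fit$n_components), tolerance = 1e-10)
  expect_true(all(diff(fit$cumulative_variance) >= -1e-10))
})

test_that("PLS recovers a planted two-parameter signal", {
  set.seed(45)
  Z <- matrix(rnorm(22 * 10), 22)
  X <- Z + 0.5 * Z[, 1]            # correlated predictors
  colnames(X) <- paste0("p", 1:10)
  y <- 3 * scale(X[, 2]) + 2 * scale(X[, 5]) + rnorm(22, 0, 0.5)
  fit <- pls_fit(X, y, n_components = 2)
  contr <- fit$contributions[, 1]
  expect_true(all(c("p2", "p5") %in%
                    names(sort(contr, decreasing = TRUE))[1:3]))
  expect_gt(sum(contr[c("p2", "p5")]), 50)
  perm <- pls_permutation_test(X, y, n_perm = 499, seed = 9)
  expect_equal(perm$p_variance, 1 / 500)
  perm2 <- pls_permutation_test(X, y, n_perm = 499, seed = 9)
  expect_identical(perm$p_variance, perm2$p_variance)
  expect_identical(perm$p_top2, perm2$p_top2)
})

test_that("PLS rejects or repairs degenerate inputs", {
  X <- cbind(a = rnorm(12), b = rep(2, 12), c = rnorm(12))
  expect_warning(fit <- pls_fit(X, rnorm(12), 1), "constant column")
  expect_identical(rownames(fit$weights), c("a", "c"))
  expect_error(pls_fit(X[, c(1, 3)], rep(1, 12), 1), "constant response")
})

test_that("correlation report matches the textbook formula", {
  tab <- data.frame(a = c(1, 2, 4, 4.5, 7, 9),
                    b = c(2, 1, 5, 3, 6, 8))
  rownames(tab) <- sprintf("S%d", 1:6)
  lags <- setNames(c(3, 4, 6, 8, 11, 14), rownames(tab))
  res <- param_lag_correlations(tab, lags)
  r_hand <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(res$r[res$parameter == "a"], r_hand(tab$a, lags),
               tolerance = 1e-12)
  expect_equal(res$r[res$parameter == "b"], r_hand(tab$b, lags),
               tolerance = 1e-12)
  # perfect and near-perfect correlations
  tab2 <- data.frame(x = 1:8, y = -(1:8) + rnorm(8, 0, 1e-4))
  rownames(tab2) <- sprintf("S%d", 1:8)
  res2 <- param_lag_correlations(tab2, setNames(1:8 + 0, rownames(tab2)))
  expect_equal(res2$r[1], 1)
  expect_lt(res2$r[2], -0.999)
  # zero-variance column flagged as NA
  tab3 <- data.frame(z = rep(1, 6)); rownames(tab3) <- rownames(tab)
  expect_true(is.na(param_lag_correlations(tab3, lags)$r))
})
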