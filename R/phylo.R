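# Phylogenetic signal, Mantel tests and phylogenetic-diversity bootstrap.

#' Pagel lambda-transformed phylogenetic covariance matrix
#'
#' The Brownian-motion covariance of a tree (diagonal: root-to-tip
#' distances; off-diagonal: shared root-to-MRCA path lengths) with every
#' off-diagonal entry multiplied by `lambda`. `lambda = 0` removes all
#' phylogenetic covariance; `lambda = 1` is plain Brownian motion.
#'
#' @param tree An [ape::phylo] tree with non-negative branch lengths and at
#'   least three tips.
#' @param lambda Signal strength in `[0, 1]`.
#' @return A symmetric positive-semidefinite tips-by-tips matrix.
#' @export
phylo_covariance <- function(tree, lambda) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths", call. = FALSE)
  if (ape::Ntip(tree) < 3L) stop("need at least 3 tips", call. = FALSE)
  if (lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]", call. = FALSE)
  C <- ape::vcv.phylo(tree)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Profile log-likelihood of trait ~ N(mu * 1, sigma2 * C(lambda)) with mu
# and sigma2 maximised analytically by GLS.
pagel_profile_ll <- function(C, y) {
  n <- length(y)
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular phylogenetic covariance (duplicate zero-length tips?); ",
         "consider jittering branch lengths", call. = FALSE))
  logdet <- 2 * sum(log(diag(ch)))
  z <- backsolve(ch, y, transpose = TRUE)
  o <- backsolve(ch, rep(1, n), transpose = TRUE)
  mu <- sum(o * z) / sum(o * o)
  r <- z - mu * o
  s2 <- sum(r * r) / n
  list(ll = -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n),
       mu = mu, sigma2 = s2)
}

#' Pagel's lambda test of phylogenetic signal
#'
#' Fits `trait ~ Normal(mu * 1, sigma2 * C(lambda))` where `C(lambda)` is
#' the [phylo_covariance()] transform; `mu` and `sigma2` are profiled
#' analytically by generalised least squares and `lambda` is maximised over
#' `[0, 1]` by bounded one-dimensional search. Signal is tested by a
#' likelihood-ratio test of `lambda = lambda_hat` against `lambda = 0` (no
#' signal). Because the null pins `lambda` at the boundary of its range,
#' the default reference distribution is the 50:50 mixture of a point mass
#' at zero and chi-square with 1 df, which keeps the test calibrated;
#' `null = "chisq1"` gives the plain chi-square convention instead.
#'
#' Trait values are matched to tips by name; tips without a trait (and
#' traits without a tip) are pruned with a message. A star phylogeny, on
#' which `lambda` has no effect, is flagged as non-identifiable and given
#' `p = 1`.
#'
#' @param tree An [ape::phylo] tree.
#' @param trait Named numeric vector of tip trait values.
#' @param null Reference distribution of the likelihood-ratio statistic:
#'   `"mixture"` (default) or `"chisq1"`.
#' @return An object of class `"pagel_lambda"`: `lambda`, `loglik_ml`,
#'   `loglik_zero`, `statistic`, `p_value`, `n_tips`, `identifiable`.
#' @export
pagel_lambda_test <- function(tree, trait, null = c("mixture", "chisq1")) {
  stopifnot(inherits(tree, "phylo"))
  null <- match.arg(null)
  if (is.null(names(trait)))
    stop("trait must be a named vector (names = tip labels)", call. = FALSE)
  trait <- trait[is.finite(trait)]   # non-finite values are missing data
  common <- intersect(tree$tip.label, names(trait))
  if (length(common) < 4L)
    stop("need at least 4 tips with trait values", call. = FALSE)
  n_pruned <- (ape::Ntip(tree) - length(common)) +
    (length(trait) - length(common))
  if (n_pruned > 0)
    message(n_pruned, " tip(s)/trait value(s) without a match were pruned")
  tree <- ape::keep.tip(tree, common)
  y <- as.numeric(trait[tree$tip.label])
  if (sd(y) == 0)
    stop("constant trait: phylogenetic signal undefined", call. = FALSE)

  C <- ape::vcv.phylo(tree)
  offdiag <- C[upper.tri(C)]
  if (all(offdiag <= max(diag(C)) * 1e-12)) {
    # star phylogeny: C(lambda) is diagonal for every lambda
    ll0 <- pagel_profile_ll(C, y)$ll
    return(structure(list(lambda = 0, loglik_ml = ll0, loglik_zero = ll0,
                          statistic = 0, p_value = 1,
                          n_tips = length(y), identifiable = FALSE,
                          null = null),
                     class = "pagel_lambda"))
  }
  ll_of <- function(lambda) {
    Cl <- C * lambda
    diag(Cl) <- diag(C)
    pagel_profile_ll(Cl, y)$ll
  }
  opt <- optimize(ll_of, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll_of(0), ll_of(1))
  lambda_hat <- cand[which.max(lls)]
  ll_ml <- max(lls)
  ll0 <- lls[2L]
  stat <- max(2 * (ll_ml - ll0), 0)
  p <- if (stat <= 0) 1 else {
    tail1 <- pchisq(stat, df = 1, lower.tail = FALSE)
    if (null == "mixture") 0.5 * tail1 else tail1
  }
  structure(list(lambda = lambda_hat, loglik_ml = ll_ml, loglik_zero = ll0,
                 statistic = stat, p_value = min(p, 1),
                 n_tips = length(y), identifiable = TRUE, null = null),
            class = "pagel_lambda")
}

#' @export
print.pagel_lambda <- function(x, ...) {
  cat("Pagel's lambda test of phylogenetic signal\n")
  cat(sprintf("  lambda = %.3f  logLik(ML) = %.3f  logLik(lambda=0) = %.3f\n",
              x$lambda, x$loglik_ml, x$loglik_zero))
  cat(sprintf("  LRT = %.3f  p = %.4g  (n = %d tips, %s null)\n",
              x$statistic, x$p_value, x$n_tips,
              if (x$null == "mixture") "mixture chi-square" else "chi-square(1)"))
  if (!x$identifiable)
    cat("  note: star phylogeny - lambda not identifiable\n")
  invisible(x)
}

#' Permutation Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with a null built by
#' simultaneously permuting rows and columns of the second matrix. The
#' one-tailed p-value is `(#{r_perm >= r_obs} + 1) / (n_perm + 1)`; the
#' two-tailed version compares absolute correlations.
#'
#' @param D1,D2 Symmetric distance matrices with zero diagonal over the same
#'   objects; if both carry dimnames, `D2` is aligned to `D1`'s labels.
#' @param n_perm Number of permutations (>= 99).
#' @param tail `"one"` (default) or `"two"`.
#' @param seed Optional integer seed for reproducible permutations.
#' @return List with `r`, `p`, `n_perm`, `tail`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, tail = c("one", "two"),
                        seed = NULL) {
  tail <- match.arg(tail)
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  for (D in list(D1, D2)) {
    if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-10 ||
        any(abs(diag(D)) > 1e-10))
      stop("distance matrices must be symmetric with zero diagonal",
           call. = FALSE)
  }
  if (!is.null(rownames(D1)) && !is.null(rownames(D2))) {
    if (!setequal(rownames(D1), rownames(D2)))
      stop("distance matrices cover different objects", call. = FALSE)
    D2 <- D2[rownames(D1), rownames(D1)]
  } else if (nrow(D1) != nrow(D2)) {
    stop("distance matrices differ in size", call. = FALSE)
  }
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  ut <- upper.tri(D1)
  v1 <- D1[ut]; v2 <- D2[ut]
  if (sd(v1) == 0 || sd(v2) == 0)
    stop("constant off-diagonal distances: correlation undefined",
         call. = FALSE)
  r_obs <- cor(v1, v2)
  if (!is.null(seed)) set.seed(seed)
  nn <- nrow(D1)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(nn)
    cor(v1, D2[p, p][ut])
  }, numeric(1))
  p <- if (tail == "one") {
    (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  } else {
    (sum(abs(r_perm) >= abs(r_obs)) + 1) / (n_perm + 1)
  }
  list(r = r_obs, p = p, n_perm = n_perm, tail = tail)
}

#' Phylogenetic diversity of a set of tips
#'
#' Total branch length of the minimal spanning subtree connecting `tips`:
#' the union of the paths from each tip to their most recent common
#' ancestor. The path from the MRCA up to the tree root is excluded unless
#' `include_root = TRUE`. For two tips this equals their patristic
#' distance; for all tips it is the sum of all branch lengths below the
#' root.
#'
#' @param tree An [ape::phylo] tree.
#' @param tips Tip labels (>= 2).
#' @param include_root Include the MRCA-to-root path (default `FALSE`).
#' @return Non-negative scalar.
#' @export
phylo_diversity <- function(tree, tips, include_root = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(tips %in% tree$tip.label))
    stop("unknown tip labels: ", paste(setdiff(tips, tree$tip.label),
                                       collapse = ", "), call. = FALSE)
  if (length(tips) < 2L) stop("need at least 2 tips", call. = FALSE)
  pd_value(tree, tips, include_root)
}

# Internal worker: walks parent pointers from each tip to the MRCA, summing
# each edge once.
pd_value <- function(tree, tips, include_root = FALSE) {
  idx <- match(tips, tree$tip.label)
  stop_node <- if (include_root) ape::Ntip(tree) + 1L
  else ape::getMRCA(tree, tips)
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen[tree$edge[, 2L]] <- tree$edge.length
  seen <- logical(max(tree$edge))
  total <- 0
  for (tip in idx) {
    node <- tip
    while (node != stop_node && !seen[node]) {
      seen[node] <- TRUE
      total <- total + elen[node]
      node <- parent[node]
      if (node == 0L) break
    }
  }
  total
}

#' Phylogenetic-diversity representativeness bootstrap
#'
#' Tests whether a chosen subset of strains captures as much phylogenetic
#' diversity (PD: total branch length of the minimal subtree spanning the
#' subset, root edge excluded) as random subsets of the same size drawn
#' from the whole tree. The p-value is the fraction of random draws with a
#' *lower* PD than the actual subset, so small p means the subset is
#' unusually concentrated (under-representative).
#'
#' @param tree An [ape::phylo] tree.
#' @param subset Tip labels, `2 <= |subset| < Ntip`.
#' @param n_draws Number of random subsets (default 1000).
#' @param seed Optional integer seed.
#' @param include_root Include the path from the subset MRCA to the tree
#'   root in PD (default `FALSE`).
#' @return List with `pd_subset`, `p`, `n_draws` and the vector `pd_draws`.
#' @export
pd_representativeness <- function(tree, subset, n_draws = 1000, seed = NULL,
                                  include_root = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(subset %in% tree$tip.label))
    stop("subset contains labels not in the tree: ",
         paste(setdiff(subset, tree$tip.label), collapse = ", "),
         call. = FALSE)
  k <- length(subset)
  if (k < 2L || k >= ape::Ntip(tree))
    stop("subset size must be in [2, Ntip - 1]", call. = FALSE)
  pd_obs <- pd_value(tree, subset, include_root)
  if (!is.null(seed)) set.seed(seed)
  pd_draws <- vapply(seq_len(n_draws), function(i) {
    pd_value(tree, sample(tree$tip.label, k), include_root)
  }, numeric(1))
  list(pd_subset = pd_obs, p = mean(pd_draws < pd_obs), n_draws = n_draws,
       pd_draws = pd_draws)
}
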