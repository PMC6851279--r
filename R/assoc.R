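# Genotype-phenotype association statistics: mutual information scans with
# max-statistic permutation correction, PLS regression of lag time on
# regulatory parameters, and simple correlation reports.

#' SNP matrix container
#'
#' Strains-by-sites matrix of allele categories (single characters; the gap
#' character `"-"` is a legitimate allele class, so indel polymorphism is
#' retained). Every retained site must be polymorphic among the retained
#' strains.
#'
#' @param alleles Character matrix, strains in rows (rownames = strain
#'   labels), sites in columns.
#' @param positions Strictly increasing 1-based alignment coordinates, one
#'   per column.
#' @return An object of class `"snp_matrix"`.
#' @export
snp_matrix <- function(alleles, positions) {
  alleles <- as.matrix(alleles)
  if (is.null(rownames(alleles)))
    stop("alleles must have strain rownames", call. = FALSE)
  if (length(positions) != ncol(alleles))
    stop("one position per site required", call. = FALSE)
  if (ncol(alleles) > 1L && any(diff(positions) <= 0))
    stop("positions must be strictly increasing", call. = FALSE)
  n_classes <- apply(alleles, 2L, function(col) length(unique(col)))
  if (any(n_classes < 2L))
    stop(sum(n_classes < 2L), " monomorphic site(s); filter before building",
         call. = FALSE)
  structure(list(alleles = alleles, positions = as.integer(positions)),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat("SNP matrix:", nrow(x$alleles), "strains x", ncol(x$alleles),
      "polymorphic sites (positions", min(x$positions), "-",
      max(x$positions), ")\n")
  invisible(x)
}

# Equal-frequency binning of a continuous vector; rank-based, so invariant
# under strictly monotone transforms (ties broken by original order).
ef_bins <- function(x, n_bins) {
  n <- length(x)
  ceiling(rank(x, ties.method = "first") * n_bins / n)
}

default_bins <- function(n) if (n < 24L) 2L else 3L

#' Mutual information between a continuous parameter and an allele class
#'
#' Plug-in mutual information (bits) between the allele category at one
#' site and the parameter discretised into `n_bins` equal-frequency bins:
#' `MI = sum p(x, y) log2(p(x, y) / (p(x) p(y)))` over the empirical joint
#' table. Equal-frequency binning makes the estimate invariant under any
#' strictly monotone transform of the parameter.
#'
#' @param param_values Continuous values, one per strain.
#' @param alleles Allele category per strain (character or factor).
#' @param n_bins Number of parameter bins; default 2 for fewer than 24
#'   strains, 3 otherwise.
#' @return Mutual information in bits (>= 0).
#' @export
mutual_information <- function(param_values, alleles, n_bins = NULL) {
  keep <- !is.na(param_values) & !is.na(alleles)
  x <- param_values[keep]; al <- as.character(alleles[keep])
  n <- length(x)
  if (n < 6L) stop("need at least 6 strains", call. = FALSE)
  if (length(unique(al)) < 2L)
    stop("monomorphic site: mutual information undefined", call. = FALSE)
  if (sd(x) == 0) {
    warning("constant parameter: mutual information is 0", call. = FALSE)
    return(0)
  }
  if (is.null(n_bins)) n_bins <- default_bins(n)
  b <- ef_bins(x, n_bins)
  tab <- table(b, al) / n
  px <- rowSums(tab); py <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log2(tab[nz] / outer(px, py)[nz]))
}

# Vectorised MI of one bin assignment against every site of an allele
# matrix. codes: integer matrix (n x S) with per-site category codes in
# 1..n_cat. Returns a length-S vector of MI in bits.
mi_all_sites <- function(b, codes, n_bins, n_cat) {
  n <- length(b)
  S <- ncol(codes)
  mi <- numeric(S)
  for (k in seq_len(n_bins)) {
    rows_k <- b == k
    pk <- sum(rows_k) / n
    if (pk == 0) next
    for (cl in seq_len(n_cat)) {
      n_kc <- colSums(codes[rows_k, , drop = FALSE] == cl)
      p_kc <- n_kc / n
      p_c <- colSums(codes == cl) / n
      nz <- p_kc > 0
      mi[nz] <- mi[nz] + p_kc[nz] * log2(p_kc[nz] / (pk * p_c[nz]))
    }
  }
  mi
}

#' Mutual-information scan with family-wise permutation correction
#'
#' Scans every polymorphic site against every parameter column. For each
#' parameter, the observed MI per site is compared with a max-statistic
#' permutation null: parameter values are permuted across strains
#' `n_perm` times and the *maximum* MI across sites is recorded per
#' permutation, giving family-wise error control across sites within a
#' parameter: `p_corrected(site) = (#{max_perm >= MI_obs(site)} + 1) /
#' (n_perm + 1)`. Linked (identical) columns necessarily share MI values
#' and significance — the linkage signature visible in real scans.
#'
#' @param params_tab Data frame, strains (rownames) x parameters.
#' @param snps A [snp_matrix()].
#' @param n_perm Permutations per parameter (>= 199).
#' @param n_bins Parameter bins (default: 2 below 24 strains, else 3).
#' @param alpha Family-wise significance cutoff (default 0.05).
#' @param seed Optional integer seed.
#' @return An object of class `"mi_scan"`: matrices `mi`, `p_corrected` and
#'   logical `significant` (parameters x sites), plus `positions`,
#'   `strains`, `n_perm`, `alpha`.
#' @export
mi_scan <- function(params_tab, snps, n_perm = 499, n_bins = NULL,
                    alpha = 0.05, seed = NULL) {
  stopifnot(inherits(snps, "snp_matrix"))
  if (n_perm < 199) stop("n_perm must be >= 199", call. = FALSE)
  strains <- intersect(rownames(params_tab), rownames(snps$alleles))
  if (length(strains) < 6L)
    stop("fewer than 6 strains shared between parameters and SNP matrix",
         call. = FALSE)
  A <- snps$alleles[strains, , drop = FALSE]
  poly <- apply(A, 2L, function(col) length(unique(col)) >= 2L)
  if (!all(poly)) {
    A <- A[, poly, drop = FALSE]
    message(sum(!poly), " site(s) monomorphic among shared strains dropped")
  }
  positions <- snps$positions[poly]
  cats <- sort(unique(as.vector(A)))
  codes <- matrix(match(A, cats), nrow = nrow(A),
                  dimnames = dimnames(A))
  n <- length(strains)
  if (is.null(n_bins)) n_bins <- default_bins(n)
  if (!is.null(seed)) set.seed(seed)

  pnames <- colnames(params_tab)
  S <- ncol(A)
  mi_mat <- p_mat <- matrix(NA_real_, length(pnames), S,
                            dimnames = list(pnames, positions))
  for (j in seq_along(pnames)) {
    x <- params_tab[strains, j]
    if (sd(x) == 0) {
      warning("constant parameter ", pnames[j], ": MI set to 0", call. = FALSE)
      mi_mat[j, ] <- 0; p_mat[j, ] <- 1
      next
    }
    b <- ef_bins(x, n_bins)
    mi_obs <- mi_all_sites(b, codes, n_bins, length(cats))
    max_perm <- vapply(seq_len(n_perm), function(i) {
      max(mi_all_sites(b[sample.int(n)], codes, n_bins, length(cats)))
    }, numeric(1))
    mi_mat[j, ] <- mi_obs
    p_mat[j, ] <- vapply(mi_obs, function(m) {
      (sum(max_perm >= m) + 1) / (n_perm + 1)
    }, numeric(1))
  }
  structure(list(mi = mi_mat, p_corrected = p_mat,
                 significant = p_mat <= alpha, positions = positions,
                 strains = strains, n_perm = n_perm, alpha = alpha,
                 n_bins = n_bins),
            class = "mi_scan")
}

#' @export
print.mi_scan <- function(x, ...) {
  cat("Mutual-information scan:", nrow(x$mi), "parameters x", ncol(x$mi),
      "sites,", length(x$strains), "strains\n")
  n_sig <- rowSums(x$significant)
  cat("  significant sites per parameter (FWER", x$alpha, "):\n")
  print(n_sig)
  invisible(x)
}

#' Partial least-squares regression of a response on correlated parameters
#'
#' PLS1 by NIPALS: predictors are z-scored and the response centred;
#' components are extracted sequentially as the direction of maximum
#' covariance with the current response residual, with deflation of X.
#' Per-component explained response variance is the reduction in residual
#' sum of squares as a percentage of the total, and the contribution of
#' variable `j` to a component is `100 * w_j^2 / sum(w^2)` (contributions
#' sum to 100 within each component). With as many components as the rank
#' of X the cumulative explained variance equals the OLS R-squared.
#'
#' @param X Numeric matrix or data frame, strains x parameters. Constant
#'   columns are dropped with a warning.
#' @param y Numeric response (e.g. lag time), one value per strain.
#' @param n_components Number of components to extract.
#' @return An object of class `"pls_fit"`: `weights` (variables x
#'   components), `contributions` (percent), `y_variance_explained`
#'   (percent per component), `cumulative_variance`, `scores`, `loadings`,
#'   `n_components` (possibly fewer than requested if X is exhausted).
#' @export
pls_fit <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  if (sd(y) == 0) stop("constant response", call. = FALSE)
  if (nrow(X) < n_components + 2L)
    stop("need at least n_components + 2 observations", call. = FALSE)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  Xc <- scale(X)
  yc <- y - mean(y)
  ss_tot <- sum(yc^2)
  p <- ncol(Xc)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, nrow(Xc), 0)
  varexp <- numeric(0)
  Xr <- Xc; yr <- yc
  for (h in seq_len(n_components)) {
    w <- crossprod(Xr, yr)
    wn <- sqrt(sum(w^2))
    if (wn <= 1e-10 * max(1, sqrt(ss_tot))) break  # X exhausted / orthogonal
    w <- w / wn
    t_h <- Xr %*% w
    tt <- sum(t_h^2)
    if (tt < 1e-24) break
    p_h <- crossprod(Xr, t_h) / tt
    q_h <- sum(yr * t_h) / tt
    Xr <- Xr - t_h %*% t(p_h)
    yr_new <- yr - q_h * t_h
    varexp <- c(varexp, 100 * (sum(yr^2) - sum(yr_new^2)) / ss_tot)
    yr <- yr_new
    W <- cbind(W, w); P <- cbind(P, p_h); Tm <- cbind(Tm, t_h)
  }
  if (ncol(W) == 0L) stop("no component could be extracted", call. = FALSE)
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("comp", seq_len(ncol(W))))
  contributions <- 100 * W^2 / matrix(colSums(W^2), nrow(W), ncol(W),
                                      byrow = TRUE)
  structure(list(weights = W, loadings = P, scores = Tm,
                 contributions = contributions,
                 y_variance_explained = setNames(varexp, colnames(W)),
                 cumulative_variance = cumsum(varexp),
                 n_components = ncol(W), variables = colnames(X)),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, digits = 3, ...) {
  cat("PLS regression:", x$n_components, "component(s)\n")
  cat("  % response variance explained:",
      paste(signif(x$y_variance_explained, digits), collapse = ", "),
      "(cumulative", signif(max(x$cumulative_variance), digits), ")\n")
  cat("  variable contributions to component 1 (%):\n")
  print(sort(round(x$contributions[, 1L], 1), decreasing = TRUE))
  invisible(x)
}

#' Permutation significance of the first PLS component
#'
#' Randomises the assignment of responses to strains `n_perm` times,
#' refits a one-component PLS each time, and compares (a) the percentage
#' of response variance explained by component 1 and (b) the summed
#' contribution of the two variables that contribute most to the observed
#' component 1 against their permutation distributions. P-values are
#' `(#{perm >= observed} + 1) / (n_perm + 1)`.
#'
#' @inheritParams pls_fit
#' @param n_perm Number of permutations (>= 199).
#' @param seed Optional integer seed.
#' @return List with `p_variance`, `p_top2`, `observed_variance`,
#'   `top2_variables`, `observed_top2_contribution`, `n_perm`.
#' @export
pls_permutation_test <- function(X, y, n_perm = 999, seed = NULL) {
  if (n_perm < 199) stop("n_perm must be >= 199", call. = FALSE)
  obs <- pls_fit(X, y, n_components = 1)
  contr <- obs$contributions[, 1L]
  top2 <- names(sort(contr, decreasing = TRUE))[1:2]
  obs_var <- obs$y_variance_explained[1L]
  obs_top2 <- sum(contr[top2])
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    f <- pls_fit(X, sample(y), n_components = 1)
    c(f$y_variance_explained[1L], sum(f$contributions[top2, 1L]))
  }, numeric(2))
  list(p_variance = (sum(perm[1L, ] >= obs_var) + 1) / (n_perm + 1),
       p_top2 = (sum(perm[2L, ] >= obs_top2) + 1) / (n_perm + 1),
       observed_variance = unname(obs_var),
       top2_variables = top2,
       observed_top2_contribution = unname(obs_top2),
       n_perm = n_perm)
}

#' Per-parameter Pearson correlations with lag time
#'
#' Plain Pearson correlation of each parameter column with the response,
#' with the two-sided t-test p-value and no multiplicity correction (the
#' number of tests performed is recorded in the output so readers can
#' adjust if desired).
#'
#' @param params_tab Data frame, strains x parameters (rownames = strains).
#' @param lags Named numeric vector of lag times (names = strains), or
#'   unnamed with one value per row of `params_tab`.
#' @return Data frame with columns `parameter`, `r`, `p`, `n`; `NA` where a
#'   parameter has zero variance or fewer than 4 paired values.
#' @export
param_lag_correlations <- function(params_tab, lags) {
  if (!is.null(names(lags))) {
    strains <- intersect(rownames(params_tab), names(lags))
    params_tab <- params_tab[strains, , drop = FALSE]
    lags <- lags[strains]
  } else if (length(lags) != nrow(params_tab)) {
    stop("lags must be named or match params_tab rows", call. = FALSE)
  }
  out <- lapply(colnames(params_tab), function(nm) {
    x <- params_tab[[nm]]
    keep <- complete.cases(x, lags)
    if (sum(keep) < 4L || sd(x[keep]) == 0 || sd(lags[keep]) == 0)
      return(data.frame(parameter = nm, r = NA_real_, p = NA_real_,
                        n = sum(keep)))
    ct <- cor.test(x[keep], lags[keep], method = "pearson")
    data.frame(parameter = nm, r = unname(ct$estimate), p = ct$p.value,
               n = sum(keep))
  })
  do.call(rbind, out)
}
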