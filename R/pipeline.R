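# End-to-end orchestration: fit -> logic -> cluster -> phylo / association
# statistics -> growth, with per-stage isolation of failures.

stage_try <- function(expr) {
  tryCatch(list(status = "ok", result = expr),
           error = function(e) list(status = paste("error:",
                                                   conditionMessage(e)),
                                    result = NULL))
}

#' Run the full analysis pipeline on a study bundle
#'
#' Executes the available stages in dependency order: landscape fitting
#' (required), logic phenotyping and clustering, phylogenetic statistics
#' (Pagel's lambda per transformed parameter plus Mantel tests, if a tree
#' is present), the mutual-information scan (if an alignment is present),
#' and growth-curve fitting with lag aggregation, PLS regression and
#' correlations (if growth data are present). Missing inputs make their
#' stages report `"skipped: ..."`; a stage error is isolated into its
#' status rather than aborting the run. All randomness derives from
#' `seed`, so reruns on the same bundle are identical.
#'
#' @param bundle A `"lac_bundle"` from [read_study_bundle()], or a
#'   directory path to one.
#' @param seed Root integer seed.
#' @param n_starts Multistart size for landscape fitting.
#' @param n_perm Permutations for Mantel, MI and PLS tests.
#' @param n_components PLS components.
#' @return An object of class `"lac_report"`: per-stage `status` plus
#'   `fits`, `params_tab`, `logic`, `dendrogram`, `phylo`, `mantel`,
#'   `mi`, `growth` entries.
#' @export
run_pipeline <- function(bundle, seed = 1, n_starts = 50, n_perm = 499,
                         n_components = 2) {
  if (is.character(bundle)) bundle <- read_study_bundle(bundle)
  if (is.null(bundle$landscapes))
    stop("bundle must contain an expression table", call. = FALSE)
  report <- list(seed = seed, status = list())

  fit_stage <- stage_try({
    fits <- lapply(seq_along(bundle$landscapes), function(i) {
      fit_landscape(bundle$landscapes[[i]], n_starts = n_starts,
                    seed = seed + i)
    })
    names(fits) <- vapply(bundle$landscapes, function(l) l$strain_id,
                          character(1))
    fits
  })
  report$status$fit <- fit_stage$status
  if (!identical(fit_stage$status, "ok"))
    stop("landscape fitting failed: ", fit_stage$status, call. = FALSE)
  fits <- fit_stage$result
  report$fits <- fits
  report$params_tab <- params_table(lapply(fits, `[[`, "params"))
  report$rmse <- vapply(fits, `[[`, numeric(1), "rmse")

  logic_stage <- stage_try({
    lp <- lapply(fits, logic_phenotype)
    do.call(rbind, lapply(lp, as.data.frame))
  })
  report$status$logic <- logic_stage$status
  report$logic <- logic_stage$result

  cluster_stage <- if (length(fits) >= 2L) stage_try({
    modeled <- lapply(fits, predict)
    list(dendrogram = cluster_landscapes(modeled),
         distances = landscape_dist_matrix(modeled))
  }) else list(status = "skipped: fewer than 2 strains", result = NULL)
  report$status$cluster <- cluster_stage$status
  report$dendrogram <- cluster_stage$result$dendrogram
  report$landscape_distances <- cluster_stage$result$distances

  ptab <- param_transform(report$params_tab)
  if (is.null(bundle$tree)) {
    report$status$phylo <- "skipped: no tree"
  } else {
    phylo_stage <- stage_try({
      sig <- lapply(colnames(ptab), function(nm) {
        tr <- setNames(ptab[[nm]], rownames(ptab))
        tryCatch(pagel_lambda_test(bundle$tree, tr),
                 error = function(e) NULL)
      })
      names(sig) <- colnames(ptab)
      res <- list(signal = sig)
      if (!is.null(report$landscape_distances)) {
        tipd <- ape::cophenetic.phylo(bundle$tree)
        common <- intersect(rownames(tipd),
                            rownames(report$landscape_distances))
        if (length(common) >= 4L) {
          set.seed(seed + 50L)
          res$mantel_tree_landscape <- mantel_test(
            tipd[common, common],
            report$landscape_distances[common, common],
            n_perm = n_perm, tail = "one")
        }
      }
      res
    })
    report$status$phylo <- phylo_stage$status
    report$phylo <- phylo_stage$result
  }

  if (is.null(bundle$snps)) {
    report$status$mi <- "skipped: no alignment"
  } else {
    mi_stage <- stage_try(
      mi_scan(ptab, bundle$snps, n_perm = n_perm, seed = seed + 60L))
    report$status$mi <- mi_stage$status
    report$mi <- mi_stage$result
  }

  if (is.null(bundle$growth_curves)) {
    report$status$growth <- "skipped: no growth data"
  } else {
    growth_stage <- stage_try({
      gfits <- lapply(seq_along(bundle$growth_curves), function(i) {
        fit_growth(bundle$growth_curves[[i]], seed = seed + 70L + i)
      })
      strains <- vapply(gfits, `[[`, character(1), "strain_id")
      lags <- vapply(split(gfits, strains), function(fs)
        aggregate_lag(fs)$lag_lambda, numeric(1))
      common <- intersect(rownames(ptab), names(lags)[!is.na(lags)])
      res <- list(fits = gfits, lags = lags)
      if (length(common) >= n_components + 2L) {
        X <- ptab[common, , drop = FALSE]
        y <- lags[common]
        res$pls <- pls_fit(X, y, n_components = n_components)
        res$pls_perm <- pls_permutation_test(X, y, n_perm = n_perm,
                                             seed = seed + 80L)
        res$correlations <- param_lag_correlations(X, y)
      }
      res
    })
    report$status$growth <- growth_stage$status
    report$growth <- growth_stage$result
  }

  class(report) <- "lac_report"
  report
}

#' @export
print.lac_report <- function(x, ...) {
  cat("lac regulation pipeline report (seed", x$seed, ")\n")
  for (nm in names(x$status)) cat(sprintf("  %-8s %s\n", nm, x$status[[nm]]))
  if (!is.null(x$rmse))
    cat(sprintf("  fitted %d strains; mean normalised RMSE %.4f\n",
                length(x$rmse), mean(x$rmse)))
  invisible(x)
}

#' Deterministic serialisable payload of a pipeline report
#'
#' Reduces a report to plain numbers and strings (dropping closures and
#' environments) so it can be written as JSON and compared byte-for-byte
#' across reruns.
#'
#' @param report A `"lac_report"`.
#' @return A JSON string.
#' @export
report_payload <- function(report) {
  stopifnot(inherits(report, "lac_report"))
  payload <- list(
    seed = report$seed,
    status = report$status,
    params = report$params_tab,
    rmse = as.list(report$rmse),
    logic = report$logic,
    merge_heights = if (!is.null(report$dendrogram))
      report$dendrogram$height,
    phylo = if (!is.null(report$phylo)) list(
      lambda = lapply(report$phylo$signal, function(s)
        if (is.null(s)) NULL else s[c("lambda", "p_value")]),
      mantel = report$phylo$mantel_tree_landscape),
    mi_significant = if (!is.null(report$mi))
      as.list(rowSums(report$mi$significant)),
    growth = if (!is.null(report$growth)) list(
      lags = as.list(report$growth$lags),
      pls_variance = report$growth$pls$y_variance_explained,
      pls_p = report$growth$pls_perm$p_variance,
      correlations = report$growth$correlations))
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
}
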