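# Inducer grids and expression landscapes.

#' Two-dimensional inducer grid
#'
#' An ordered grid of cAMP (mM) and IPTG (uM) concentrations over which
#' expression is measured or predicted.
#'
#' @param camp_mM Strictly increasing, non-negative cAMP concentrations (mM);
#'   at least two levels.
#' @param iptg_uM Strictly increasing, non-negative IPTG concentrations (uM);
#'   at least two levels.
#' @return An object of class `"inducer_grid"`.
#' @export
inducer_grid <- function(camp_mM, iptg_uM) {
  for (v in list(camp_mM, iptg_uM)) {
    if (length(v) < 2L || any(v < 0) || any(diff(v) <= 0) || any(!is.finite(v)))
      stop("grid axes must be strictly increasing, non-negative, length >= 2",
           call. = FALSE)
  }
  structure(list(camp_mM = as.numeric(camp_mM), iptg_uM = as.numeric(iptg_uM)),
            class = "inducer_grid")
}

#' The standard assay grid: 8 cAMP x 10 IPTG concentrations
#'
#' cAMP at 0, 0.625, 1.25, 2.5, 5, 10, 20 and 40 mM; IPTG at 0, 0.78, 1.56,
#' 3.125, 6.25, 12.5, 25, 50, 100 and 200 uM — the two-fold dilution series
#' used in the expression assays this package models.
#'
#' @return An `inducer_grid` with 8 cAMP and 10 IPTG levels.
#' @export
default_grid <- function() {
  inducer_grid(camp_mM = c(0, 0.625, 1.25, 2.5, 5, 10, 20, 40),
               iptg_uM = c(0, 0.78, 1.56, 3.125, 6.25, 12.5, 25, 50, 100, 200))
}

#' Expression landscape over an inducer grid
#'
#' Holds mean background-subtracted expression (arbitrary fluorescence
#' units) of one strain at every cAMP x IPTG combination, with optional
#' replicate counts and standard deviations. Values are indexed
#' `[camp, iptg]` (rows follow `grid$camp_mM`). Negative values (possible
#' after background subtraction) are clamped to zero with a warning;
#' missing cells may be `NA` and are masked during fitting.
#'
#' @param strain_id Strain label.
#' @param grid An [inducer_grid()].
#' @param values Numeric matrix, `length(camp_mM)` rows x `length(iptg_uM)`
#'   columns.
#' @param n_replicates Optional matrix of replicate counts.
#' @param sd Optional matrix of replicate standard deviations.
#' @return An object of class `"expression_landscape"`.
#' @export
expression_landscape <- function(strain_id, grid, values,
                                 n_replicates = NULL, sd = NULL) {
  stopifnot(inherits(grid, "inducer_grid"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(grid$camp_mM), length(grid$iptg_uM))))
    stop("values must be a ", length(grid$camp_mM), " x ",
         length(grid$iptg_uM), " matrix matching the grid", call. = FALSE)
  if (any(is.infinite(values)))
    stop("expression values must be finite or NA", call. = FALSE)
  n_neg <- sum(values < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warning(n_neg, " negative expression value(s) clamped to 0 for strain ",
            strain_id, call. = FALSE)
    values[!is.na(values) & values < 0] <- 0
  }
  dimnames(values) <- list(camp_mM = grid$camp_mM, iptg_uM = grid$iptg_uM)
  structure(list(strain_id = strain_id, grid = grid, values = values,
                 n_replicates = n_replicates, sd = sd),
            class = "expression_landscape")
}

#' @export
print.expression_landscape <- function(x, ...) {
  cat("Expression landscape for strain", x$strain_id, "\n")
  cat(" grid:", length(x$grid$camp_mM), "cAMP levels x",
      length(x$grid$iptg_uM), "IPTG levels\n")
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(" expression range: %.3g - %.3g AFU (%d missing cells)\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

same_grid <- function(g1, g2) {
  isTRUE(all.equal(g1$camp_mM, g2$camp_mM)) &&
    isTRUE(all.equal(g1$iptg_uM, g2$iptg_uM))
}
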