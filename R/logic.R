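# Regulatory logic phenotyping and landscape comparison.

#' Logic phenotype of an input function
#'
#' Summarises the shape of a two-inducer expression landscape by its corner
#' behaviour. The landscape is rescaled so its maximum equals 100; "low" and
#' "high" are the smallest and largest concentration on each axis. The three
#' log-ratio statistics are
#' `pi_i = log10(max(E_i, 1)) / log10(100)` for the corners
#' (low IPTG, low cAMP), (high IPTG, low cAMP) and (low IPTG, high cAMP),
#' relative to the (high, high) corner which is pinned at 1. Low values of
#' all three indicate AND-type logic (expression only with both inducers).
#' The single-inducer fractions are `f_iptg = E(highI, lowC) / E(highI, highC)`
#' and `f_camp = E(lowI, highC) / E(highI, highC)`, and
#' `synergy = 1 - (f_iptg + f_camp - f_iptg * f_camp)` is the share of
#' maximal expression not explained by an independent (Bliss-type)
#' combination of the two single-inducer effects.
#'
#' @param x An [expression_landscape()] or a fitted [fit_landscape()] model
#'   (in which case the model-predicted landscape on the fitted grid is
#'   phenotyped).
#' @param ... Unused.
#' @return An object of class `"logic_phenotype"`: a list with `pi1`, `pi2`,
#'   `pi3`, `f_iptg`, `f_camp`, `synergy` and `strain_id`.
#' @examples
#' grid <- inducer_grid(c(0, 40), c(0, 200))
#' ls <- expression_landscape("demo", grid,
#'                            matrix(c(1, 21, 57, 100), 2, 2, byrow = TRUE))
#' logic_phenotype(ls)
#' @export
logic_phenotype <- function(x, ...) UseMethod("logic_phenotype")

#' @export
logic_phenotype.expression_landscape <- function(x, ...) {
  v <- x$values
  if (any(is.na(v)))
    stop("logic phenotype requires a complete landscape", call. = FALSE)
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("need at least two levels per inducer axis", call. = FALSE)
  mx <- max(v)
  if (mx <= 0)
    stop("degenerate (all-zero) landscape: logic phenotype undefined",
         call. = FALSE)
  v <- v / mx * 100
  # rows index cAMP, columns index IPTG
  e_ll <- v[1L, 1L]                  # low IPTG,  low cAMP
  e_hl <- v[1L, ncol(v)]             # high IPTG, low cAMP
  e_lh <- v[nrow(v), 1L]             # low IPTG,  high cAMP
  e_hh <- v[nrow(v), ncol(v)]        # high IPTG, high cAMP
  pi_of <- function(e) log10(max(e, 1)) / log10(100)
  f_iptg <- e_hl / e_hh
  f_camp <- e_lh / e_hh
  structure(list(strain_id = x$strain_id,
                 pi1 = pi_of(e_ll), pi2 = pi_of(e_hl), pi3 = pi_of(e_lh),
                 f_iptg = f_iptg, f_camp = f_camp,
                 synergy = 1 - (f_iptg + f_camp - f_iptg * f_camp)),
            class = "logic_phenotype")
}

#' @export
logic_phenotype.lacfit <- function(x, ...) {
  logic_phenotype(predict_landscape(x$landscape$grid, x$params,
                                    strain_id = x$landscape$strain_id))
}

#' @export
print.logic_phenotype <- function(x, digits = 3, ...) {
  cat("Logic phenotype", if (!is.null(x$strain_id)) paste0("(", x$strain_id, ")"), "\n")
  cat(sprintf("  pi1 = %.*f  pi2 = %.*f  pi3 = %.*f\n",
              digits, x$pi1, digits, x$pi2, digits, x$pi3))
  cat(sprintf("  f_iptg = %.*f  f_camp = %.*f  synergy = %.*f\n",
              digits, x$f_iptg, digits, x$f_camp, digits, x$synergy))
  invisible(x)
}

#' @export
as.data.frame.logic_phenotype <- function(x, ...) {
  data.frame(strain = x$strain_id, pi1 = x$pi1, pi2 = x$pi2, pi3 = x$pi3,
             f_iptg = x$f_iptg, f_camp = x$f_camp, synergy = x$synergy)
}

#' Euclidean distance between two expression landscapes
#'
#' Landscapes are first max-normalised (each divided by its own maximum) so
#' that shape, not absolute fluorescence scale, is compared; the distance is
#' the Euclidean norm of the difference of the flattened value matrices.
#'
#' @param ls1,ls2 [expression_landscape()] objects on an identical grid.
#' @param normalize Divide each landscape by its own maximum first
#'   (default `TRUE`).
#' @return Non-negative scalar; zero iff the (normalised) landscapes agree.
#' @export
landscape_distance <- function(ls1, ls2, normalize = TRUE) {
  stopifnot(inherits(ls1, "expression_landscape"),
            inherits(ls2, "expression_landscape"))
  if (!same_grid(ls1$grid, ls2$grid))
    stop("landscapes are on different inducer grids", call. = FALSE)
  v1 <- ls1$values; v2 <- ls2$values
  if (normalize) {
    v1 <- v1 / max(v1, na.rm = TRUE)
    v2 <- v2 / max(v2, na.rm = TRUE)
  }
  sqrt(sum((v1 - v2)^2, na.rm = TRUE))
}

#' Pairwise landscape distance matrix
#'
#' @param landscapes List of [expression_landscape()] objects on a shared
#'   grid.
#' @inheritParams landscape_distance
#' @return A symmetric labelled distance matrix.
#' @export
landscape_dist_matrix <- function(landscapes, normalize = TRUE) {
  k <- length(landscapes)
  if (k < 2L) stop("need at least two landscapes", call. = FALSE)
  labs <- vapply(landscapes, function(l) l$strain_id, character(1))
  D <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      D[i, j] <- D[j, i] <- landscape_distance(landscapes[[i]],
                                               landscapes[[j]],
                                               normalize = normalize)
    }
  }
  D
}

#' Hierarchically cluster expression landscapes
#'
#' Average-linkage (UPGMA) clustering on the pairwise [landscape_distance()]
#' matrix. Merge heights equal the average distance between the merged
#' groups, so dendrogram height is on the landscape-distance scale.
#'
#' @inheritParams landscape_dist_matrix
#' @return An [stats::hclust] object labelled by strain.
#' @export
cluster_landscapes <- function(landscapes, normalize = TRUE) {
  D <- landscape_dist_matrix(landscapes, normalize = normalize)
  hclust(as.dist(D), method = "average")
}
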