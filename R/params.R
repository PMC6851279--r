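# Parameter container for the thermodynamic input-function model.

PARAM_NAMES <- c("alpha", "gamma", "a", "b", "d", "eta", "n", "m",
                 "Km_cAMP", "Km_IPTG")

#' Regulatory parameters of the thermodynamic lac promoter model
#'
#' Bundles the ten parameters of the promoter-occupancy model of the lac
#' input function: maximum and basal expression rates (`alpha`, `gamma`,
#' arbitrary fluorescence units), thermodynamic binding weights for RNA
#' polymerase alone (`a`), the LacI repressor (`b`) and the cAMP-CRP
#' activator complex (`d`), the fold-stabilisation of polymerase binding by
#' bound cAMP-CRP (`eta`), Hill cooperativities of cAMP-CRP binding (`n`)
#' and IPTG-LacI binding (`m`), and the half-saturation constants
#' `Km_cAMP` (mM) and `Km_IPTG` (uM).
#'
#' @param alpha Maximum expression rate (AFU, > 0).
#' @param gamma Basal expression rate (AFU, >= 0).
#' @param a RNA-polymerase binding weight without cAMP-CRP (> 0).
#' @param b LacI binding weight (>= 0).
#' @param d cAMP-CRP binding weight (>= 0).
#' @param eta Fold-stabilisation of polymerase binding by cAMP-CRP (> 0).
#' @param n Hill exponent of cAMP-CRP binding (> 0).
#' @param m Hill exponent of IPTG-LacI binding (> 0).
#' @param Km_cAMP Half-saturation constant of cAMP on CRP (mM, > 0).
#' @param Km_IPTG Dissociation constant of IPTG from LacI (uM, > 0).
#'
#' @return An object of class `"regulatory_params"`: a named numeric vector
#'   of length ten.
#' @examples
#' p <- regulatory_params(alpha = 1000, gamma = 10, a = 0.05, b = 50,
#'                        d = 10, eta = 20, n = 2, m = 2,
#'                        Km_cAMP = 5, Km_IPTG = 20)
#' predict_expression(camp = 5, iptg = 100, params = p)
#' @export
regulatory_params <- function(alpha, gamma, a, b, d, eta, n, m,
                              Km_cAMP, Km_IPTG) {
  p <- c(alpha = alpha, gamma = gamma, a = a, b = b, d = d, eta = eta,
         n = n, m = m, Km_cAMP = Km_cAMP, Km_IPTG = Km_IPTG)
  validate_params(p)
  structure(p, class = "regulatory_params")
}

validate_params <- function(p) {
  p <- unclass(p)
  if (!is.numeric(p) || length(p) != 10L || !all(PARAM_NAMES %in% names(p)))
    stop("regulatory parameters must be 10 named numeric values", call. = FALSE)
  if (any(!is.finite(p)))
    stop("regulatory parameters must be finite", call. = FALSE)
  strict_pos <- c("alpha", "a", "eta", "n", "m", "Km_cAMP", "Km_IPTG")
  if (any(p[strict_pos] <= 0))
    stop("parameters ", paste(strict_pos[p[strict_pos] <= 0], collapse = ", "),
         " must be > 0", call. = FALSE)
  if (any(p[c("gamma", "b", "d")] < 0))
    stop("gamma, b and d must be >= 0", call. = FALSE)
  invisible(p)
}

as_params <- function(x) {
  if (inherits(x, "regulatory_params")) return(x)
  x <- unlist(x)
  do.call(regulatory_params, as.list(x[PARAM_NAMES]))
}

#' @export
print.regulatory_params <- function(x, digits = 4, ...) {
  cat("Regulatory parameters (thermodynamic lac promoter model):\n")
  print(signif(unclass(x), digits))
  invisible(x)
}

#' @export
as.data.frame.regulatory_params <- function(x, ...) {
  as.data.frame(as.list(unclass(x)))
}

#' Convert a list of parameter sets to a strains-by-parameters table
#'
#' @param params_list Named list of `regulatory_params` (names are strain
#'   labels).
#' @return A data frame with one row per strain and the ten model parameters
#'   as columns.
#' @export
params_table <- function(params_list) {
  stopifnot(length(params_list) >= 1)
  out <- do.call(rbind, lapply(params_list, function(p) unclass(as_params(p))))
  out <- as.data.frame(out)
  rownames(out) <- names(params_list)
  out
}

#' Default analysis-scale transform of the parameter table
#'
#' Parameters spanning decades (rates, binding weights, half-saturation
#' constants) are log10-transformed; the Hill cooperativities `n` and `m`
#' stay linear. Used before mutual-information scans, PLS regression and
#' correlation reports.
#'
#' @param tab Data frame as returned by [params_table()].
#' @return Data frame of the same shape with transformed columns, renamed
#'   `log_<param>` where a log was taken.
#' @export
param_transform <- function(tab) {
  logged <- c("alpha", "gamma", "a", "b", "d", "eta", "Km_cAMP", "Km_IPTG")
  out <- tab
  for (nm in intersect(logged, colnames(tab))) {
    out[[nm]] <- log10(pmax(tab[[nm]], .Machine$double.xmin))
  }
  colnames(out) <- ifelse(colnames(out) %in% logged,
                          paste0("log_", colnames(out)), colnames(out))
  out
}
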