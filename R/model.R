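# The thermodynamic (statistical-mechanics) model of the lac input function.
#
# Occupancy of the promoter by RNA polymerase is weighted by a alone, by
# d*A(C) for bound cAMP-CRP, and by a*d*eta*A(C) for the doubly-bound,
# eta-fold stabilised state; repression enters as an independent factor
# 1/(1 + b*R(I)). DNA-looping states are deliberately omitted.

#' CRP activity: fraction of CRP bound to cAMP
#'
#' Hill saturation of CRP by cAMP, `A(C) = C^n / (Km_cAMP^n + C^n)`.
#'
#' @param camp cAMP concentration(s), mM, >= 0.
#' @param params A [regulatory_params()] object (uses `n`, `Km_cAMP`).
#' @return Fraction in `[0, 1]`, monotone non-decreasing in `camp`.
#' @export
crp_activity <- function(camp, params) {
  params <- as_params(params)
  if (any(camp < 0)) stop("cAMP concentration must be >= 0", call. = FALSE)
  # (Km/C)^n form is better conditioned than C^n/(Km^n + C^n) for large C
  out <- ifelse(camp > 0,
                1 / (1 + (params[["Km_cAMP"]] / camp)^params[["n"]]),
                0)
  unname(out)
}

#' LacI activity: fraction of LacI not bound by IPTG
#'
#' `R(I) = 1 / (1 + (I / Km_IPTG)^m)`: full repressor activity without
#' inducer, declining with a Hill coefficient `m`.
#'
#' @param iptg IPTG concentration(s), uM, >= 0.
#' @param params A [regulatory_params()] object (uses `m`, `Km_IPTG`).
#' @return Fraction in `[0, 1]`, monotone non-increasing in `iptg`.
#' @export
laci_activity <- function(iptg, params) {
  params <- as_params(params)
  if (any(iptg < 0)) stop("IPTG concentration must be >= 0", call. = FALSE)
  unname(1 / (1 + (iptg / params[["Km_IPTG"]])^params[["m"]]))
}

#' Predicted expression at one inducer combination
#'
#' Composes CRP activity `A`, LacI activity `R`, the polymerase-occupancy
#' (activation) factor and the repression factor into expression
#' `G(C, I) = gamma + alpha * P_act(C) * F_rep(I)` with
#' `P_act = (a + a d eta A) / (1 + a + d A + a d eta A)` and
#' `F_rep = 1 / (1 + b R)`. Expression is bounded in
#' `[gamma, gamma + alpha]` and, for `eta >= 1`, non-decreasing in both
#' inducers.
#'
#' @param camp cAMP (mM, >= 0); vectorised.
#' @param iptg IPTG (uM, >= 0); vectorised (recycled against `camp`).
#' @param params A [regulatory_params()] object.
#' @return Expression in AFU.
#' @export
predict_expression <- function(camp, iptg, params) {
  params <- as_params(params)
  A <- crp_activity(camp, params)
  R <- laci_activity(iptg, params)
  a <- params[["a"]]; d <- params[["d"]]; eta <- params[["eta"]]
  act <- a + a * d * eta * A
  p_act <- act / (1 + a + d * A + a * d * eta * A)
  f_rep <- 1 / (1 + params[["b"]] * R)
  unname(params[["gamma"]] + params[["alpha"]] * p_act * f_rep)
}

#' Predict a full expression landscape
#'
#' Element-wise application of [predict_expression()] over an
#' [inducer_grid()].
#'
#' @param grid An [inducer_grid()].
#' @param params A [regulatory_params()] object.
#' @param strain_id Label attached to the returned landscape.
#' @return An [expression_landscape()] of model-predicted values.
#' @export
predict_landscape <- function(grid, params, strain_id = "model") {
  stopifnot(inherits(grid, "inducer_grid"))
  params <- as_params(params)
  cc <- grid$camp_mM
  ii <- grid$iptg_uM
  vals <- outer(cc, ii, function(C, I) predict_expression(C, I, params))
  expression_landscape(strain_id, grid, vals)
}
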