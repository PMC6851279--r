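# Multistart nonlinear least-squares fitting of the promoter model.

# Log10-uniform start ranges for the multistart; alpha and gamma are scaled
# to the observed maximum so the same ranges serve any fluorescence scale.
param_start_ranges <- function(data_max) {
  list(alpha   = c(0.1, 3) * data_max,
       gamma   = c(1e-4, 0.5) * data_max,
       a       = c(1e-3, 1e4),
       b       = c(1e-3, 1e4),
       d       = c(1e-3, 1e4),
       eta     = c(1, 1e3),
       n       = c(0.5, 6),
       m       = c(0.5, 6),
       Km_cAMP = c(0.05, 100),
       Km_IPTG = c(0.1, 1000))
}

params_from_log <- function(theta) {
  p <- exp(theta)
  names(p) <- PARAM_NAMES
  structure(p, class = "regulatory_params")
}

#' Fit the thermodynamic promoter model to an expression landscape
#'
#' Estimates the ten [regulatory_params()] by minimising the
#' root-mean-square error between observed and predicted expression, both
#' divided by the observed maximum (so the objective and the reported RMSE
#' are on a 0-1 normalised scale and invariant to fluorescence units).
#' Parameters are optimised in log space to enforce positivity. The search
#' runs a Latin-hypercube multistart of derivative-free Nelder-Mead local
#' searches over documented log-uniform ranges, then polishes the best
#' solution (simplex restarts followed by a quasi-Newton refinement). The
#' whole procedure is deterministic given `seed`.
#'
#' @param landscape An [expression_landscape()]; must have at least as many
#'   non-missing cells as free parameters and a positive maximum. `NA`
#'   cells are masked from the objective.
#' @param n_starts Number of multistart points (default 50).
#' @param seed Integer seed controlling the start draw.
#' @param scale Objective scale: `"linear"` (normalised AFU, default) or
#'   `"log10"`.
#' @param max_eval Maximum objective evaluations per local search.
#' @param tol Relative convergence tolerance of each local search.
#' @return An object of class `"lacfit"` with elements `params`
#'   ([regulatory_params()]), `rmse` (normalised linear-scale RMSE),
#'   `n_starts`, `n_converged`, `best_objective`, `best_trace` (best
#'   objective so far after each start), `weakly_identified` (parameters
#'   whose +/-10% perturbation changes the objective by < 1e-6), `seed` and
#'   the fitted `landscape`.
#' @seealso [goodness_of_fit()], [logic_phenotype()], [predict.lacfit()]
#' @export
fit_landscape <- function(landscape, n_starts = 50, seed = 1,
                          scale = c("linear", "log10"),
                          max_eval = 5000, tol = 1e-10) {
  stopifnot(inherits(landscape, "expression_landscape"))
  scale <- match.arg(scale)
  obs <- landscape$values
  keep <- !is.na(obs)
  if (sum(keep) < 10L)
    stop("landscape has fewer observed cells than free parameters",
         call. = FALSE)
  M <- max(obs, na.rm = TRUE)
  if (M <= 0)
    stop("unfittable landscape: all observed expression is zero",
         call. = FALSE)
  obs_n <- obs / M
  cc <- landscape$grid$camp_mM
  ii <- landscape$grid$iptg_uM

  # A(C) and R(I) depend only on (n, Km_cAMP) and (m, Km_IPTG); evaluate the
  # landscape directly from the log-parameter vector to keep the objective
  # cheap inside the multistart.
  pred_n <- function(theta) {
    p <- exp(theta)
    A <- ifelse(cc > 0, 1 / (1 + (p[9L] / cc)^p[7L]), 0)
    R <- 1 / (1 + (ii / p[10L])^p[8L])
    p_act <- (p[3L] + p[3L] * p[5L] * p[6L] * A) /
      (1 + p[3L] + p[5L] * A + p[3L] * p[5L] * p[6L] * A)
    f_rep <- 1 / (1 + p[4L] * R)
    (p[2L] + p[1L] * outer(p_act, f_rep)) / M
  }
  raw_objective <- if (scale == "linear") {
    function(theta) {
      g <- pred_n(theta)
      sqrt(mean((obs_n[keep] - g[keep])^2))
    }
  } else {
    function(theta) {
      g <- pred_n(theta)
      sqrt(mean((log10(pmax(obs_n[keep], 1e-4)) -
                   log10(pmax(g[keep], 1e-4)))^2))
    }
  }
  # keep the search inside a wide box (6 decades beyond the start ranges):
  # unbounded simplex excursions along non-identifiable directions would
  # otherwise overflow exp(theta)
  box_lo <- NULL; box_hi <- NULL  # set after ranges are known
  objective <- function(theta) {
    excess <- sum(pmax(box_lo - theta, 0)) + sum(pmax(theta - box_hi, 0))
    if (excess > 0) return(1e3 * (1 + excess))
    v <- raw_objective(theta)
    if (is.finite(v)) v else 1e6
  }

  ranges <- param_start_ranges(M)
  lo <- log(vapply(ranges, `[`, numeric(1), 1L))
  hi <- log(vapply(ranges, `[`, numeric(1), 2L))
  box_lo <- lo - 6 * log(10)
  box_hi <- hi + 6 * log(10)
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, 10L)
  starts <- sweep(sweep(u, 2L, hi - lo, `*`), 2L, lo, `+`)

  vals <- rep(NA_real_, n_starts)
  sols <- vector("list", n_starts)
  n_conv <- 0L
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      optim(starts[s, ], objective, method = "Nelder-Mead",
            control = list(maxit = max_eval, reltol = tol)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    vals[s] <- fit$value
    sols[[s]] <- fit$par
    if (fit$convergence == 0L) n_conv <- n_conv + 1L
  }
  if (all(is.na(vals)))
    stop("no multistart point converged; landscape may be degenerate",
         call. = FALSE)
  best <- which.min(vals)  # ties broken by lowest start index
  theta <- sols[[best]]
  value <- vals[best]

  # polish: simplex restarts until stalled, then quasi-Newton refinement
  for (r in 1:4) {
    fit <- optim(theta, objective, method = "Nelder-Mead",
                 control = list(maxit = max_eval, reltol = tol))
    if (fit$value < value - 1e-13) {
      theta <- fit$par; value <- fit$value
    } else break
  }
  nb <- tryCatch(nlminb(theta, objective, lower = box_lo, upper = box_hi,
                        control = list(iter.max = 500, abs.tol = 0)),
                 error = function(e) NULL)
  if (!is.null(nb) && is.finite(nb$objective) && nb$objective < value) {
    theta <- nb$par; value <- nb$objective
  }

  # weak-identifiability probe: +/-10% parameter perturbation
  weak <- character(0)
  for (j in seq_along(PARAM_NAMES)) {
    dj <- numeric(10L); dj[j] <- log(1.1)
    dv <- max(abs(objective(theta + dj) - value),
              abs(objective(theta - dj) - value))
    if (dv < 1e-6) weak <- c(weak, PARAM_NAMES[j])
  }

  params <- params_from_log(theta)
  structure(list(params = params,
                 rmse = goodness_of_fit(landscape, params),
                 n_starts = n_starts,
                 n_converged = n_conv,
                 best_objective = value,
                 best_trace = cummin(ifelse(is.na(vals), Inf, vals)),
                 weakly_identified = weak,
                 scale = scale,
                 seed = seed,
                 landscape = landscape),
            class = "lacfit")
}

#' Normalised RMSE of a parameter set against an observed landscape
#'
#' Root-mean-square error over all observed grid cells, with both observed
#' and predicted values divided by the observed maximum; zero iff the model
#' reproduces the data exactly, and invariant to rescaling the landscape's
#' fluorescence units.
#'
#' @param landscape An [expression_landscape()].
#' @param params A [regulatory_params()] object.
#' @return Non-negative scalar RMSE on the normalised scale.
#' @export
goodness_of_fit <- function(landscape, params) {
  stopifnot(inherits(landscape, "expression_landscape"))
  params <- as_params(params)
  obs <- landscape$values
  M <- max(obs, na.rm = TRUE)
  if (!is.finite(M) || M <= 0)
    stop("landscape maximum must be positive", call. = FALSE)
  pred <- predict_landscape(landscape$grid, params)$values
  keep <- !is.na(obs)
  sqrt(mean(((obs[keep] - pred[keep]) / M)^2))
}

#' @export
print.lacfit <- function(x, digits = 4, ...) {
  cat("Thermodynamic input-function fit: strain", x$landscape$strain_id, "\n")
  cat(sprintf("  normalised RMSE: %.4g (objective %.4g on %s scale)\n",
              x$rmse, x$best_objective, x$scale))
  cat(sprintf("  multistart: %d/%d local searches converged (seed %d)\n",
              x$n_converged, x$n_starts, x$seed))
  print(signif(unclass(x$params), digits))
  if (length(x$weakly_identified))
    cat("  weakly identified:", paste(x$weakly_identified, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.lacfit <- function(object, ...) unclass(object$params)

#' @export
summary.lacfit <- function(object, ...) {
  lp <- logic_phenotype(object)
  out <- list(fit = object, logic = lp)
  class(out) <- "summary.lacfit"
  out
}

#' @export
print.summary.lacfit <- function(x, ...) {
  print(x$fit)
  print(x$logic)
  invisible(x)
}

#' Predict expression from a fitted model
#'
#' @param object A `"lacfit"` object.
#' @param newdata Optional data frame with columns `camp_mM` and `iptg_uM`;
#'   if omitted, the fitted grid is used and a full landscape is returned.
#' @param ... Unused.
#' @return A numeric vector (with `newdata`) or an
#'   [expression_landscape()] of predicted AFU.
#' @export
predict.lacfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(predict_landscape(object$landscape$grid, object$params,
                             strain_id = object$landscape$strain_id))
  predict_expression(newdata$camp_mM, newdata$iptg_uM, object$params)
}

#' @export
fitted.lacfit <- function(object, ...) {
  predict_landscape(object$landscape$grid, object$params)$values
}

#' @export
residuals.lacfit <- function(object, ...) {
  object$landscape$values - fitted(object)
}

#' Simulate replicate noisy landscapes from a fitted model
#'
#' Draws `nsim` replicate-averaged landscapes from the fitted model under
#' multiplicative lognormal measurement noise (see [simulate_landscape()]).
#'
#' @param object A `"lacfit"` object.
#' @param nsim Number of simulated landscapes.
#' @param seed Integer seed.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Replicates averaged per simulated landscape.
#' @param ... Unused.
#' @return A list of [expression_landscape()] objects.
#' @export
simulate.lacfit <- function(object, nsim = 1, seed = 1, noise_cv = 0.05,
                            n_replicates = 3, ...) {
  lapply(seq_len(nsim), function(i) {
    simulate_landscape(object$params, grid = object$landscape$grid,
                       noise_cv = noise_cv, n_replicates = n_replicates,
                       seed = seed + i - 1L,
                       strain_id = object$landscape$strain_id)$landscape
  })
}

#' Plot observed and fitted expression against IPTG
#'
#' One curve per cAMP level: points are observed expression, lines the
#' fitted model, both against IPTG on a log-like axis.
#'
#' @param x A `"lacfit"` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.lacfit <- function(x, ...) {
  ii <- x$landscape$grid$iptg_uM
  xs <- log10(ii + min(ii[ii > 0]) / 2)
  obs <- t(x$landscape$values)
  fit <- t(fitted(x))
  matplot(xs, obs, pch = 16, xlab = "log10 IPTG (uM, shifted)",
          ylab = "expression (AFU)",
          main = paste("lac input function:", x$landscape$strain_id), ...)
  matplot(xs, fit, type = "l", lty = 1, add = TRUE)
  invisible(x)
}
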