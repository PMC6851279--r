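# Modified Gompertz growth model and lag-time extraction.

#' Modified Gompertz growth function
#'
#' `y(t) = baseline + A_max * exp(-exp((mu_max * e / A_max) * (lag_lambda - t) + 1))`.
#' The tangent at the inflection point has slope `mu_max` and crosses
#' `y = baseline` at `t = lag_lambda`, so `lag_lambda` is the lag time: the
#' delay before the culture reaches its maximum growth rate.
#'
#' @param t Time (min); vectorised.
#' @param A_max Asymptotic OD gain above baseline (> 0).
#' @param mu_max Maximum growth rate (OD/min, > 0).
#' @param lag_lambda Lag time (min).
#' @param baseline Initial OD.
#' @return OD at `t`.
#' @export
gompertz <- function(t, A_max, mu_max, lag_lambda, baseline = 0) {
  if (A_max <= 0) stop("A_max must be > 0", call. = FALSE)
  if (mu_max <= 0) stop("mu_max must be > 0", call. = FALSE)
  baseline + A_max * exp(-exp(mu_max * exp(1) / A_max * (lag_lambda - t) + 1))
}

#' Growth curve container
#'
#' @param well_id Well label.
#' @param strain_id Strain label.
#' @param times Strictly increasing times (min), length >= 10.
#' @param od Finite OD readings, same length as `times`.
#' @return An object of class `"growth_curve"`.
#' @export
growth_curve <- function(well_id, strain_id, times, od) {
  if (length(times) != length(od))
    stop("times and od must have equal length", call. = FALSE)
  if (length(times) < 10L)
    stop("need at least 10 time points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(od)))
    stop("od readings must be finite", call. = FALSE)
  structure(list(well_id = well_id, strain_id = strain_id,
                 times = as.numeric(times), od = as.numeric(od)),
            class = "growth_curve")
}

#' Fit the modified Gompertz model to a growth curve
#'
#' Least-squares fit of [gompertz()] by Levenberg-Marquardt from
#' data-driven starting values (baseline from the low OD quantile, maximum
#' slope of a lightly smoothed curve for `mu_max` and the tangent
#' construction for the lag), with jittered restarts. A curve whose OD
#' range is below `min_range` is flagged as no-growth and rejected rather
#' than raising an error, as are curves where no start converges.
#'
#' @param curve A [growth_curve()].
#' @param min_range Minimum OD range to attempt a fit (default 0.02).
#' @param n_starts Number of jittered restarts (default 4).
#' @param seed Seed for the start jitter.
#' @return An object of class `"gompertz_fit"`: `A_max`, `mu_max`,
#'   `lag_lambda`, `baseline`, `rmse`, `weight` (`1 / rmse^2`), `accepted`
#'   flag and rejection `reason` (if any).
#' @export
fit_growth <- function(curve, min_range = 0.02, n_starts = 4, seed = 1) {
  stopifnot(inherits(curve, "growth_curve"))
  t <- curve$times; y <- curve$od
  rejected <- function(reason) {
    structure(list(well_id = curve$well_id, strain_id = curve$strain_id,
                   A_max = NA_real_, mu_max = NA_real_,
                   lag_lambda = NA_real_, baseline = NA_real_,
                   rmse = NA_real_, weight = NA_real_,
                   accepted = FALSE, reason = reason),
              class = "gompertz_fit")
  }
  if (diff(range(y)) < min_range) return(rejected("no growth"))

  b0 <- as.numeric(quantile(y, 0.02))
  A0 <- max(y) - b0
  k <- min(5L, length(y))
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  slope <- diff(as.numeric(ys)) / diff(t)
  iok <- which(is.finite(slope))
  imax <- iok[which.max(slope[iok])]
  mu0 <- max(slope[imax], A0 / diff(range(t)))
  lag0 <- max(t[imax] - (y[imax] - b0) / mu0, 0)

  set.seed(seed)
  starts <- rbind(c(A0, mu0, lag0, b0),
                  t(replicate(max(n_starts - 1L, 0L),
                              c(A0 * runif(1, 0.5, 1.5),
                                mu0 * runif(1, 0.3, 2),
                                lag0 * runif(1, 0.5, 1.5),
                                b0 + A0 * runif(1, -0.05, 0.05)))))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    st <- starts[s, ]
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ gompertz(t, A, mu, lag, b),
        start = list(A = st[1], mu = st[2], lag = st[3], b = st[4]),
        lower = c(A = 1e-6, mu = 1e-9, lag = 0, b = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(rejected("no converged fit"))
  cf <- coef(best$fit)
  rmse <- sqrt(best$rss / length(y))
  structure(list(well_id = curve$well_id, strain_id = curve$strain_id,
                 A_max = unname(cf["A"]), mu_max = unname(cf["mu"]),
                 lag_lambda = unname(cf["lag"]), baseline = unname(cf["b"]),
                 rmse = rmse, weight = 1 / max(rmse, 1e-10)^2,
                 accepted = TRUE, reason = NA_character_),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz fit:", x$strain_id, "/", x$well_id, "\n")
  if (!x$accepted) {
    cat("  rejected:", x$reason, "\n")
  } else {
    cat(sprintf("  A_max = %.4g OD  mu_max = %.4g OD/min  lag = %.1f min  rmse = %.3g\n",
                x$A_max, x$mu_max, x$lag_lambda, x$rmse))
  }
  invisible(x)
}

#' Aggregate replicate lag estimates for one strain
#'
#' Weighted mean of the per-replicate lag times using the fit-quality
#' weights `1 / rmse^2`; rejected fits are excluded. The reported
#' uncertainty is the weighted standard error of the mean (`NA` with a
#' single accepted replicate). With no accepted fits a missing-value result
#' is returned rather than an error.
#'
#' @param fits List of [fit_growth()] results for one strain.
#' @return List with `lag_lambda`, `se`, `n_accepted` and `n_total`.
#' @export
aggregate_lag <- function(fits) {
  acc <- Filter(function(f) isTRUE(f$accepted), fits)
  if (length(acc) == 0L)
    return(list(lag_lambda = NA_real_, se = NA_real_,
                n_accepted = 0L, n_total = length(fits)))
  lag <- vapply(acc, `[[`, numeric(1), "lag_lambda")
  w <- vapply(acc, `[[`, numeric(1), "weight")
  wm <- sum(w * lag) / sum(w)
  se <- if (length(acc) > 1L) {
    sqrt(sum(w * (lag - wm)^2) / sum(w) / (length(acc) - 1L))
  } else NA_real_
  list(lag_lambda = wm, se = se,
       n_accepted = length(acc), n_total = length(fits))
}
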