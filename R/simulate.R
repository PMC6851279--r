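# Synthetic-data generators with known ground truth: regulatory parameters,
# noisy expression landscapes, trees with Brownian traits, SNP matrices with
# planted causal sites, and Gompertz growth panels whose lag depends on
# chosen regulatory parameters.

#' Simulation configuration
#'
#' Collects every knob of the synthetic study in one object. Defaults
#' emulate the measured study design: the standard 8 x 10 inducer grid,
#' 5% multiplicative measurement noise with 3 replicates, ~20 strains,
#' ~300 polymorphic sites with one planted causal site (plus exact-copy
#' linked sites), and growth lag linear in z-scored log a (negative) and
#' log eta (positive).
#'
#' @param seed Root integer seed; every generator is a pure function of it.
#' @param n_strains Number of strains.
#' @param grid [inducer_grid()] for expression simulation.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise.
#' @param n_replicates Replicates averaged per landscape.
#' @param lambda_true Pagel's lambda used when simulating traits on the
#'   tree.
#' @param n_sites,n_causal,n_linked,effect_size,maf_range SNP-matrix
#'   settings: total sites, causal sites, exact-copy linked sites per
#'   causal site, allele-parameter separation (in SD units; controls the
#'   label-noise flip rate) and the minor-allele-frequency range of
#'   neutral sites.
#' @param causal_param Parameter column driving the causal site(s).
#' @param lag_beta0,lag_beta_a,lag_beta_eta,lag_sigma Growth-lag model:
#'   `lag = beta0 + beta_a * z(log10 a) + beta_eta * z(log10 eta) + noise`
#'   (minutes), floored at zero.
#' @param od_noise Gaussian OD reading noise (sd).
#' @param correlate_a_eta Impose the negative correlation between log a and
#'   log eta seen in fitted strains (Gaussian copula, `rho_a_eta`).
#' @param rho_a_eta Latent correlation used when `correlate_a_eta`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, n_strains = 20, grid = default_grid(),
                       noise_cv = 0.05, n_replicates = 3, lambda_true = 1,
                       n_sites = 300, n_causal = 1, n_linked = 4,
                       effect_size = 3, maf_range = c(0.2, 0.5),
                       causal_param = "Km_IPTG",
                       lag_beta0 = 400, lag_beta_a = -60, lag_beta_eta = 60,
                       lag_sigma = 30, od_noise = 0.002,
                       correlate_a_eta = TRUE, rho_a_eta = -0.7) {
  cfg <- list(seed = as.integer(seed), n_strains = n_strains, grid = grid,
              noise_cv = noise_cv, n_replicates = n_replicates,
              lambda_true = lambda_true, n_sites = n_sites,
              n_causal = n_causal, n_linked = n_linked,
              effect_size = effect_size, maf_range = maf_range,
              causal_param = causal_param, lag_beta0 = lag_beta0,
              lag_beta_a = lag_beta_a, lag_beta_eta = lag_beta_eta,
              lag_sigma = lag_sigma, od_noise = od_noise,
              correlate_a_eta = correlate_a_eta, rho_a_eta = rho_a_eta)
  stopifnot(cfg$n_strains >= 0, cfg$noise_cv >= 0, cfg$n_replicates >= 1,
            cfg$n_sites >= 1, inherits(grid, "inducer_grid"))
  class(cfg) <- "sim_config"
  cfg
}

# Generator-scale parameter ranges: binding weights, cooperativities and
# half-saturation constants reuse the fitting start ranges; the expression
# rates are drawn on a realistic absolute AFU scale.
sample_ranges <- function() {
  r <- param_start_ranges(1)
  r$alpha <- c(200, 5000)
  r$gamma <- c(0.5, 50)
  r
}

#' Draw regulatory parameter sets for synthetic strains
#'
#' Log-uniform draws over the documented parameter ranges. With
#' `correlate_a_eta` the `a` and `eta` draws share a negatively correlated
#' Gaussian copula, reproducing the negative a-eta association that fitted
#' strains display.
#'
#' @param n_strains Number of strains (0 returns an empty list).
#' @param seed Integer seed.
#' @param correlate_a_eta Logical.
#' @param rho_a_eta Latent copula correlation (< 0).
#' @return Named list of [regulatory_params()] (names `S01`, `S02`, ...).
#' @export
sample_params <- function(n_strains, seed = 1, correlate_a_eta = TRUE,
                          rho_a_eta = -0.7) {
  if (n_strains == 0L) return(setNames(list(), character(0)))
  set.seed(seed)
  ranges <- sample_ranges()
  u <- matrix(runif(n_strains * 10L), n_strains, 10L,
              dimnames = list(NULL, PARAM_NAMES))
  if (correlate_a_eta) {
    z1 <- qnorm(u[, "a"])
    z2 <- rho_a_eta * z1 + sqrt(1 - rho_a_eta^2) * qnorm(u[, "eta"])
    u[, "eta"] <- pnorm(z2)
  }
  out <- lapply(seq_len(n_strains), function(i) {
    vals <- vapply(PARAM_NAMES, function(nm) {
      lo <- log10(ranges[[nm]][1L]); hi <- log10(ranges[[nm]][2L])
      10^(lo + u[i, nm] * (hi - lo))
    }, numeric(1))
    do.call(regulatory_params, as.list(vals))
  })
  names(out) <- sprintf("S%02d", seq_len(n_strains))
  out
}

#' Simulate a replicate-averaged noisy expression landscape
#'
#' The noiseless truth is [predict_landscape()]; each replicate cell is the
#' truth multiplied by lognormal noise `exp(N(0, sigma))` with `sigma`
#' chosen so the multiplicative coefficient of variation equals
#' `noise_cv`. The returned landscape averages the replicates and records
#' per-cell replicate counts and standard deviations.
#'
#' @param params A [regulatory_params()] object.
#' @param grid An [inducer_grid()].
#' @param noise_cv Multiplicative noise CV (>= 0).
#' @param n_replicates Number of replicates averaged.
#' @param seed Integer seed.
#' @param strain_id Label for the landscape.
#' @return List with `landscape` (noisy, averaged) and `truth` (noiseless).
#' @export
simulate_landscape <- function(params, grid = default_grid(),
                               noise_cv = 0.05, n_replicates = 3,
                               seed = 1, strain_id = "sim") {
  truth <- predict_landscape(grid, params, strain_id = strain_id)
  set.seed(seed)
  sigma <- sqrt(log(1 + noise_cv^2))
  dims <- dim(truth$values)
  reps <- array(NA_real_, c(dims, n_replicates))
  for (r in seq_len(n_replicates)) {
    reps[, , r] <- truth$values *
      exp(matrix(rnorm(prod(dims), 0, sigma), dims[1L], dims[2L]))
  }
  avg <- apply(reps, c(1L, 2L), mean)
  sds <- if (n_replicates > 1L) apply(reps, c(1L, 2L), sd) else NULL
  list(landscape = expression_landscape(
         strain_id, grid, avg,
         n_replicates = matrix(n_replicates, dims[1L], dims[2L]), sd = sds),
       truth = truth,
       replicates = reps)
}

#' Simulate a tree and tip traits with known phylogenetic signal
#'
#' Pure-birth (Yule) tree scaled to unit depth; traits drawn from
#' `Normal(mu * 1, sigma2 * C(lambda_true))` via the Cholesky factor of the
#' lambda-transformed covariance.
#'
#' @param n_strains Number of tips (>= 3).
#' @param lambda_true Pagel's lambda of the simulated traits.
#' @param seed Integer seed.
#' @param n_traits Number of independent trait vectors.
#' @param mu,sigma2 Trait mean and Brownian rate.
#' @param tip_labels Optional tip labels (default `S01`, ...).
#' @return List with `tree` ([ape::phylo]) and `traits` (matrix tips x
#'   traits with tip rownames).
#' @export
simulate_tree_and_traits <- function(n_strains, lambda_true = 1, seed = 1,
                                     n_traits = 1, mu = 0, sigma2 = 1,
                                     tip_labels = NULL) {
  if (n_strains < 3L) stop("need at least 3 strains", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_strains, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(n_strains)])
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- if (is.null(tip_labels))
    sprintf("S%02d", seq_len(n_strains)) else tip_labels
  C <- phylo_covariance(tree, lambda_true)
  R <- chol(sigma2 * C)
  traits <- mu + crossprod(R, matrix(rnorm(n_strains * n_traits),
                                     n_strains, n_traits))
  rownames(traits) <- tree$tip.label
  colnames(traits) <- paste0("trait", seq_len(n_traits))
  list(tree = tree, traits = traits)
}

#' Simulate a bi-allelic SNP matrix with planted causal sites
#'
#' Causal sites are assigned by splitting the strains at the median of the
#' chosen parameter and flipping a fixed number of labels,
#' `round(n * pnorm(-effect_size / 2))`, at random positions (so
#' `effect_size` is the group separation in SD units and the planted
#' mutual information is exactly controllable). Each causal site gets
#' `n_linked` exact-copy linked sites, reproducing the linkage signature of
#' real scans. Remaining sites are neutral binomial draws with minor-allele
#' frequency in `maf_range`; monomorphic draws are regenerated.
#'
#' @param params_tab Data frame strains x parameters (rownames = strains).
#' @param n_sites Total sites.
#' @param n_causal Causal sites.
#' @param n_linked Exact copies per causal site.
#' @param effect_size Separation in SD units (0 = no planted signal).
#' @param maf_range Neutral minor-allele-frequency range.
#' @param causal_param Parameter column to plant on.
#' @param seed Integer seed.
#' @return List with `snps` (a [snp_matrix()]) and `registry` (data frame
#'   of planted causal/linked site positions; empty when
#'   `effect_size = 0`).
#' @export
simulate_snp_matrix <- function(params_tab, n_sites = 300, n_causal = 1,
                                n_linked = 4, effect_size = 3,
                                maf_range = c(0.2, 0.5),
                                causal_param = colnames(params_tab)[1L],
                                seed = 1) {
  n <- nrow(params_tab)
  if (n < 6L) stop("need at least 6 strains", call. = FALSE)
  set.seed(seed)
  draw_neutral <- function() {
    repeat {
      maf <- runif(1, maf_range[1L], maf_range[2L])
      col <- rbinom(n, 1L, maf)
      if (length(unique(col)) >= 2L) return(col)
    }
  }
  n_planted <- n_causal * (1L + n_linked)
  if (n_planted > n_sites)
    stop("n_sites too small for the planted sites", call. = FALSE)
  x <- params_tab[[causal_param]]
  cols <- matrix(0L, n, n_sites)
  planted_idx <- if (n_causal > 0L && effect_size > 0) {
    sort(sample.int(n_sites, n_planted))
  } else integer(0)
  registry <- NULL
  if (length(planted_idx)) {
    p_flip <- pnorm(-effect_size / 2)
    groups <- split(planted_idx,
                    rep(seq_len(n_causal), each = 1L + n_linked))
    n_flip <- round(n * p_flip)   # deterministic count: MI is controllable
    registry <- do.call(rbind, lapply(seq_along(groups), function(g) {
      repeat {
        al <- as.integer(x > median(x))
        flip <- sample.int(n, n_flip)
        al[flip] <- 1L - al[flip]
        if (length(unique(al)) >= 2L) break
      }
      for (idx in groups[[g]]) cols[, idx] <<- al
      data.frame(site = groups[[g]],
                 role = c("causal", rep("linked", n_linked)),
                 group = g, param = causal_param)
    }))
  }
  for (idx in setdiff(seq_len(n_sites), planted_idx))
    cols[, idx] <- draw_neutral()
  alleles <- matrix(c("a", "g")[cols + 1L], n, n_sites,
                    dimnames = list(rownames(params_tab), NULL))
  positions <- sort(sample.int(6298L, n_sites))
  if (!is.null(registry)) registry$position <- positions[registry$site]
  list(snps = snp_matrix(alleles, positions),
       registry = if (is.null(registry))
         data.frame(site = integer(0), role = character(0),
                    group = integer(0), param = character(0),
                    position = integer(0)) else registry)
}

#' Simulate a growth panel whose lag depends on regulatory parameters
#'
#' True lag per strain is
#' `beta0 + beta_a * z(log10 a) + beta_eta * z(log10 eta) + N(0, sigma)`,
#' floored at zero; each strain gets `n_replicates` Gompertz curves (OD450
#' read every 3 min for 24 h) with Gaussian reading noise.
#'
#' @param params_tab Data frame strains x parameters with columns `a` and
#'   `eta`.
#' @param beta0,beta_a,beta_eta,sigma Lag-model coefficients (minutes).
#' @param n_replicates Wells per strain.
#' @param od_noise OD reading noise sd.
#' @param seed Integer seed.
#' @return List with `curves` (list of [growth_curve()]) and `true_lags`
#'   (named vector, minutes).
#' @export
simulate_growth_panel <- function(params_tab, beta0 = 400, beta_a = -60,
                                  beta_eta = 60, sigma = 30,
                                  n_replicates = 3, od_noise = 0.002,
                                  seed = 1) {
  strains <- rownames(params_tab)
  set.seed(seed)
  za <- as.numeric(scale(log10(params_tab$a)))
  ze <- as.numeric(scale(log10(params_tab$eta)))
  lag <- pmax(beta0 + beta_a * za + beta_eta * ze +
                rnorm(length(strains), 0, sigma), 0)
  names(lag) <- strains
  times <- seq(0, 1440, by = 3)
  curves <- list()
  for (i in seq_along(strains)) {
    for (r in seq_len(n_replicates)) {
      A <- rnorm(1, 0.5, 0.02)
      mu <- rnorm(1, 0.004, 3e-4)
      od <- gompertz(times, A, mu, lag[i], baseline = 0.02) +
        rnorm(length(times), 0, od_noise)
      curves[[length(curves) + 1L]] <-
        growth_curve(paste0(strains[i], "_r", r), strains[i], times, od)
    }
  }
  list(curves = curves, true_lags = lag)
}

#' Simulate a complete synthetic study with known ground truth
#'
#' Draws regulatory parameters for `n_strains` strains, noisy expression
#' landscapes on the configured grid, a unit-depth pure-birth phylogeny
#' with traits of known signal, a SNP matrix with planted causal and linked
#' sites, and a growth panel whose lag follows the configured linear model.
#' Stage seeds are derived deterministically from the root seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `"lac_study"`: `config`, `params`
#'   (list), `params_tab`, `landscapes`, `truths`, `tree`, `traits`,
#'   `snps`, `snp_registry`, `growth_curves`, `true_lags`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$seed
  params <- sample_params(config$n_strains, seed = s,
                          correlate_a_eta = config$correlate_a_eta,
                          rho_a_eta = config$rho_a_eta)
  tab <- params_table(params)
  sims <- lapply(seq_along(params), function(i) {
    simulate_landscape(params[[i]], grid = config$grid,
                       noise_cv = config$noise_cv,
                       n_replicates = config$n_replicates,
                       seed = s + 1000L + i, strain_id = names(params)[i])
  })
  tt <- simulate_tree_and_traits(config$n_strains,
                                 lambda_true = config$lambda_true,
                                 seed = s + 2000L,
                                 tip_labels = names(params))
  snp <- simulate_snp_matrix(tab, n_sites = config$n_sites,
                             n_causal = config$n_causal,
                             n_linked = config$n_linked,
                             effect_size = config$effect_size,
                             maf_range = config$maf_range,
                             causal_param = config$causal_param,
                             seed = s + 3000L)
  gp <- simulate_growth_panel(tab, beta0 = config$lag_beta0,
                              beta_a = config$lag_beta_a,
                              beta_eta = config$lag_beta_eta,
                              sigma = config$lag_sigma,
                              n_replicates = config$n_replicates,
                              od_noise = config$od_noise,
                              seed = s + 4000L)
  structure(list(config = config, params = params, params_tab = tab,
                 landscapes = lapply(sims, `[[`, "landscape"),
                 truths = lapply(sims, `[[`, "truth"),
                 replicates = lapply(sims, `[[`, "replicates"),
                 tree = tt$tree, traits = tt$traits,
                 snps = snp$snps, snp_registry = snp$registry,
                 growth_curves = gp$curves, true_lags = gp$true_lags),
            class = "lac_study")
}

#' @export
print.lac_study <- function(x, ...) {
  cat("Synthetic lac regulation study (seed", x$config$seed, "):",
      x$config$n_strains, "strains\n")
  cat(" ", length(x$landscapes), "landscapes,",
      ncol(x$snps$alleles), "SNP sites,",
      length(x$growth_curves), "growth curves\n")
  invisible(x)
}
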