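# Shared fixtures: a representative parameter set, small grids, and a
# random parameter draw used by property-style tests.

demo_params <- function() {
  regulatory_params(alpha = 1000, gamma = 10, a = 0.05, b = 50, d = 10,
                    eta = 20, n = 2, m = 2, Km_cAMP = 5, Km_IPTG = 20)
}

small_grid <- function() inducer_grid(camp_mM = c(0, 1, 10, 40),
                                      iptg_uM = c(0, 5, 50, 200))

# Log-uniform random draw over the documented ranges (independent of
# sample_params, so generator tests have something to compare against).
random_params <- function() {
  lu <- function(lo, hi) 10^runif(1, log10(lo), log10(hi))
  regulatory_params(alpha = lu(200, 5000), gamma = lu(0.5, 50),
                    a = lu(1e-3, 1e4), b = lu(1e-3, 1e4), d = lu(1e-3, 1e4),
                    eta = lu(1, 1e3), n = lu(0.5, 6), m = lu(0.5, 6),
                    Km_cAMP = lu(0.05, 100), Km_IPTG = lu(0.1, 1000))
}

# Corner-value landscape on a 2x2 grid (values indexed [camp, iptg]).
corner_landscape <- function(ll, hl, lh, hh, strain = "corner") {
  expression_landscape(strain, inducer_grid(c(0, 40), c(0, 200)),
                       matrix(c(ll, lh, hl, hh), 2, 2))
}
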