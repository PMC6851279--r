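---
title: "Modelling lac regulatory input functions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lac regulatory input functions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lacreg)
```

This vignette explains the models and statistical procedures `lacreg`
implements, the assumptions behind them, the tunable parameters that
matter, and the design choices made where several reasonable options
existed. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` compute.

## The thermodynamic promoter model

The *lac* promoter integrates two diffusible signals. cAMP binds CRP; the
cAMP-CRP complex binds upstream of the promoter and stabilises RNA
polymerase. IPTG binds the LacI repressor and releases it from its
operators. `predict_expression()` composes four elementary quantities:

* CRP activity `A(C) = C^n / (Km_cAMP^n + C^n)`, the fraction of CRP
  bound to cAMP, a Hill saturation with cooperativity `n` and
  half-saturation `Km_cAMP` (mM);
* LacI activity `R(I) = 1 / (1 + (I/Km_IPTG)^m)`, the fraction of LacI
  *not* bound by IPTG, declining with cooperativity `m` around the
  dissociation constant `Km_IPTG` (µM);
* a promoter-occupancy (activation) factor derived from a three-state
  thermodynamic partition — promoter empty, polymerase bound (weight
  `a`), cAMP-CRP bound (weight `d·A`), both bound with stabilisation `η`
  (weight `a·d·η·A`):
  `P_act = (a + a·d·η·A) / (1 + a + d·A + a·d·η·A)`;
* an independent repression factor `F_rep = 1 / (1 + b·R)` with LacI
  binding weight `b`.

Expression is `G = γ + α·P_act·F_rep`, bounded in `[γ, γ + α]` and, for
`η ≥ 1`, non-decreasing in both inducers. The model deliberately omits
DNA looping by LacI tetramers and inducer-exclusion or metabolic
feedbacks: it is the minimal statistical-mechanics description able to
express the observed spectrum from AND-like behaviour (expression only
with both inducers) to single-input dominance. Setting `b = 0` makes the
landscape flat along the IPTG axis and `d = 0` flat along the cAMP axis;
these limits are tested as properties.

Two symbols deserve comment. The binding weights of cAMP-CRP and of LacI
are distinct parameters here, named `d` and `b`; and the repression
factor multiplies the activation factor rather than entering the same
partition function — a committed algebraic choice kept behind the single
function boundary of `predict_expression()`, so an alternative algebra
can be swapped in without touching any other stage.

## Logic phenotypes

`logic_phenotype()` works on the landscape's four corner conditions,
"low" and "high" being the smallest and largest measured concentration on
each axis (0 and 40 mM cAMP, 0 and 200 µM IPTG on the standard grid).
Because a ratio of logarithms depends on units, the landscape is first
rescaled so its maximum equals 100 and corner values are clamped to at
least 1; then `π_i = log10(E_i)/log10(100)`, pinning the (high, high)
corner at 1. A constant landscape therefore has `π = (1, 1, 1)`,
`f_IPTG = f_cAMP = 1` and `synergy = 0`; an ideal AND landscape has
`π = (0, 0, 0)` and synergy near 1. The rescaling is a convention of this
package, chosen to make `π` comparable across strains whose absolute
fluorescence scales differ.

`synergy = 1 − (f_IPTG + f_cAMP − f_IPTG·f_cAMP)` measures the share of
maximal expression not explained by a Bliss-independent combination of
the single-inducer effects; it can be slightly negative when the
combination underperforms independence.

## Fitting

`fit_landscape()` minimises the RMSE between observed and predicted
landscapes, both divided by the observed maximum, so the objective is on
a 0–1 scale and invariant to fluorescence units; a `log10` objective is
available via `scale = "log10"`. All ten parameters are optimised as
logarithms, enforcing positivity. The search is a Latin-hypercube
multistart (default 50 starts) of Nelder–Mead simplex searches over
log-uniform ranges spanning the measured concentration decades
(`a, b, d ∈ [1e-3, 1e4]`, `η ∈ [1, 1e3]`, `n, m ∈ [0.5, 6]`,
`Km_cAMP ∈ [0.05, 100]` mM, `Km_IPTG ∈ [0.1, 1000]` µM, with α and γ
scaled to the data maximum), followed by simplex restarts and a bounded
quasi-Newton polish of the best solution. The search is confined to a box
six decades beyond the start ranges; excursions outside it would overflow
the exponentials along softly non-identifiable directions without
improving the fit. Ties between equally good starts are broken by start
index, and the whole procedure is a pure function of the seed.

Identifiability: the ten-parameter model fitted to an 8 × 10 grid has
well-known soft non-identifiabilities (e.g. trade-offs between `a`, `d`
and `η` when the landscape saturates). `fit_landscape()` probes each
parameter with a ±10% perturbation and flags parameters whose objective
change is below 1e-6 as weakly identified. For this reason recovery is
assessed on predicted landscapes and logic phenotypes, not on raw
parameter values, and the acceptance suite requires `f_IPTG`, `f_cAMP`
and synergy within ±0.05 of truth for at least 90% of simulated strains.

## Landscape distance and clustering

`landscape_distance()` max-normalises each landscape and takes the
Euclidean norm of the difference, comparing shape rather than absolute
output; normalisation can be disabled. `cluster_landscapes()` applies
average-linkage (UPGMA) clustering, so dendrogram heights are mean
landscape distances between groups.

## Phylogenetic statistics

`pagel_lambda_test()` fits `trait ~ Normal(μ·1, σ²·C(λ))`, where `C(λ)`
multiplies the off-diagonal of the Brownian-motion covariance by λ. μ and
σ² are profiled analytically by GLS through a Cholesky factorisation; λ
is maximised over `[0, 1]` by bounded one-dimensional search, with the
endpoints checked explicitly. Restricting λ to `[0, 1]` keeps `C(λ)`
positive definite on any tree; estimates at the boundary are reported as
such.

The signal test is a likelihood-ratio test of λ̂ against λ = 0. Because
the null pins λ at the boundary of the parameter space, the plain
χ²₁ reference is conservative; the default reference is therefore the
50:50 mixture of a point mass at zero and χ²₁, the standard boundary
correction (`null = "chisq1"` restores the plain convention). Even the
mixture remains conservative in finite samples: on a 64-tip unit-depth
pure-birth tree the white-noise λ̂ sits exactly at 0 in roughly 80% of
replicates rather than the asymptotic 50%, so the realised test size at
nominal 5% is near 1.5–2%. This is a property of the test itself — the
reference implementation in the field behaves identically — and the
package documents it rather than inflating the statistic. Power against
Brownian traits on such trees is essentially complete. A star phylogeny
makes λ unidentifiable; the test flags this and returns `p = 1`.

`mantel_test()` correlates upper triangles of two distance matrices and
builds its null by simultaneous row/column permutation, with
`p = (#{r_perm ≥ r_obs} + 1)/(n_perm + 1)` (one-tailed; the two-tailed
variant compares absolute values). `pd_representativeness()` computes
phylogenetic diversity as the total branch length of the minimal subtree
spanning a tip subset, excluding the path above the subset's MRCA
(`include_root = TRUE` includes it, for the alternative convention), and
bootstraps equal-size random subsets; `p` is the fraction of draws with
*lower* PD, so small values flag unrepresentative, clade-concentrated
subsets.

## Association statistics

`mutual_information()` uses the plug-in estimator on the joint table of
the allele class and the parameter discretised into equal-frequency bins
(2 bins below 24 strains, 3 otherwise). With ~20 strains the plug-in
estimator is bias-dominated, so few, balanced bins are the defensible
choice; rank-based binning additionally makes the estimate invariant
under any strictly monotone transform of the parameter, so the log
transforms used elsewhere cannot change a scan. Gap characters are a
legitimate allele class: indel polymorphism is information.

`mi_scan()` controls the family-wise error across sites within each
parameter by the max-statistic permutation null: parameter values are
permuted across strains and the maximum MI over all sites recorded per
permutation. This is the standard scan correction and reproduces the flat
significance profile that linkage produces — identical (linked) columns
necessarily share MI and significance. Corrected p-values are monotone in
observed MI by construction and never zero.

`pls_fit()` implements PLS1 by NIPALS on z-scored predictors and a
centred response: each component is the direction of maximal covariance
with the current response residual, with X deflation. Per-component
explained response variance is the reduction in residual sum of squares
(as % of total); with as many components as the predictor rank the
cumulative value equals the OLS R², an identity the tests verify to
1e-8. Variable contributions are squared normalised weights, summing to
100% per component. `pls_permutation_test()` permutes the response,
refits one component, and reports permutation p-values both for the
explained variance and for the summed contribution of the two variables
leading the observed component. By default the association stages log10
parameters spanning decades (α, γ, a, b, d, η, and both Km) and keep the
Hill exponents linear (`param_transform()`).

## Growth curves

`gompertz()` is the modified (Zwietering) Gompertz function
`y(t) = baseline + A·exp(−exp((μe/A)(λ_lag − t) + 1))`, parameterised so
the tangent at the inflection has slope μ (the maximum growth rate,
OD/min) and crosses the baseline at `t = λ_lag` — the lag time, i.e. the
delay before the culture reaches its maximum growth rate. The baseline is
fitted as a fourth parameter. `fit_growth()` uses Levenberg–Marquardt
least squares from data-driven starts (low-quantile baseline, maximum
smoothed slope, tangent-derived lag) with jittered restarts; curves whose
OD range is below 0.02 are flagged no-growth and rejected rather than
erroring. Replicate lags are combined by `aggregate_lag()` with weights
`1/rmse²` — "weighted by fit quality" made concrete as inverse squared
residual error — with a weighted standard error.

## The synthetic-data generator

`simulate_study()` emulates the measured study design with known ground
truth; its defaults are the study conditions the tests run under:

* expression on the standard 8 cAMP × 10 IPTG grid, multiplicative
  lognormal measurement noise with 5% CV (fluorescence noise is
  scale-proportional), 3 replicates averaged;
* regulatory parameters drawn log-uniformly from the fitting ranges, with
  α ∈ [200, 5000] and γ ∈ [0.5, 50] AFU as a realistic reporter scale,
  and an optional negative Gaussian-copula correlation (ρ = −0.7) between
  `log a` and `log η`, matching the trade-off fitted strains display;
* a unit-depth pure-birth phylogeny with traits drawn from
  `Normal(μ·1, σ²C(λ_true))` via Cholesky;
* ~300 bi-allelic sites over a 6.3 kb coordinate frame: one causal site
  assigned by a median split of a chosen parameter with a fixed number of
  label flips, `round(n·pnorm(−effect/2))`, so the planted mutual
  information is an exactly controllable function of the effect size; each
  causal site carries exact-copy linked sites (the linkage signature), the
  rest are neutral draws with MAF in [0.2, 0.5], regenerated if
  monomorphic;
* growth lag linear in z-scored `log a` (−60 min per SD) and `log η`
  (+60 min per SD) around 400 min with 30 min strain noise — lags of a
  few hundred minutes and effects comfortably above replicate noise, as
  in glucose-to-lactose transition experiments — with three replicate
  Gompertz curves per strain (OD read every 3 min for 24 h, reading noise
  0.002 OD).

What the generator does *not* emulate: flow-cytometry measurement
artefacts and gating, day/block effects, sequence evolution (sites are
exchangeable draws, not substitution-model output), diauxie or other
multi-phase growth, and any mechanistic genotype-to-parameter map — the
causal-site construction is a statistical convenience that plants a
detectable association, not a biophysical model. Passing tests therefore
demonstrate correctness and calibration of the estimators under the
stated noise model, not robustness to everything real data can do.

## Numerical choices and degenerate inputs

Background-subtracted negative fluorescence values are clamped to zero at
load time with a warning count. Incomplete grids are accepted; missing
cells are masked from the fitting objective. All-zero landscapes are
unfittable and error; constant landscapes fit flat with every direction
flagged weakly identified. Equal multistart optima resolve to the lowest
start index. Permutation p-values use the add-one convention and cannot
be zero. Every stochastic routine takes an explicit seed and is
bit-reproducible; `run_pipeline()` derives per-stage seeds from one root
seed, and `report_payload()` serialises a run to JSON for byte-level
comparison of reruns.

Problem sizes used by the test and acceptance runs — 20 strains for
recovery, 500/200 replicates for test-size/power simulation, 200 scans
for family-wise calibration, 999 (or 199–499 where nested) permutations —
were chosen to give binomial confidence intervals tight enough to detect
miscalibration while keeping a full run in the minutes range on a single
CPU.

## Known limitations

* Individual parameters are reported with a weak-identifiability flag,
  not confidence intervals; no posterior or profile-likelihood intervals
  are computed.
* The λ likelihood-ratio test is conservative at the boundary (above);
  reported p-values err on the safe side.
* The MI estimator's absolute value is bin-dependent; only comparisons
  within a scan (and their permutation p-values) are interpretable.
* Replicate-level expression error is averaged, not modelled; no
  measurement-error propagation into fitted parameters.
* The pipeline assumes one landscape per strain and complete replicate
  exchangeability.
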