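---
title: "Models and methods behind macrosem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind macrosem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrosem)
```

## The scientific question

Species richness varies enormously across space, and three non-exclusive
mechanisms are commonly invoked to explain it: current climate may set the
carrying capacity of regions directly; climate may act indirectly by raising
or lowering *speciation rates*; or regions may differ in the *evolutionary
time* over which they have accumulated lineages. macrosem implements the
analysis pipeline used to weigh these hypotheses against one another on a
gridded assemblage: per-cell richness from species ranges, per-cell means of
tip-level speciation-rate and evolutionary-time metrics averaged over a set
of stochastically completed phylogenies, and a candidate set of piecewise
structural equation models (pSEMs) whose every equation is a
simultaneous-autoregressive (SAR) spatial error regression, ranked by AICc.

All user-facing functions take tibbles and return tibbles, fitted objects
support `tidy()`, `glance()` and `autoplot()`, and a `run_pipeline()`
orchestrator reproduces an entire run from a YAML configuration and one seed.

## The spatial frame

`make_grid()` builds a planar grid of square cells (default 100 km),
row-major cell ids starting at 0, centroids at `((col + 0.5)s, (row + 0.5)s)`.
Working on a planar frame emulates an equal-area projection by construction:
all distances are Euclidean in km. `filter_land_cells()` drops cells below a
land-coverage threshold (default 25%, the boundary value is kept), and
`build_pam()` assembles the presence-absence matrix restricted to retained
cells, warning about (not silently removing) species whose ranges fall
entirely on dropped cells.

**Climate-change velocity.** For each paleo snapshot, the temporal rate
`|current − paleo| / age` (units/yr) is divided by the local spatial gradient
of the current layer (units/km), and the per-snapshot velocities are
averaged. The spatial gradient is the Euclidean magnitude
`sqrt(gx² + gy²)` of the central-difference gradient, with one-sided
differences at edges — the convention under which a plane of slope 0.01
units/km crossed at 0.001 units/yr moves at exactly 0.1 km/yr. Flat terrain
is floored at `gradient_floor` (default 1e-6 units/km, reported via a
message) because the ratio is otherwise undefined; the floor value is a
deliberate, configurable numerical guard rather than a scientific claim.
Velocity uses the absolute temporal change: sign conventions add nothing
once snapshots are averaged. When several climate variables are available
the function is applied per supplied layer; averaging across layers is left
to the caller's configuration.

**Normalization.** `normalize_cells()` z-scores every covariate with the
*population* standard deviation (divide by n). The choice is arbitrary at
the sample sizes involved but documented so that hand-computed checks are
exact; scaling constants are stored and `denormalize_cells()` inverts the
transform. Raw richness is kept alongside its z-scored copy `richness_z`, the
modelling response.

## Tip metrics over imputed trees

The per-species speciation-rate statistic is DR, the reciprocal of the
equal-splits measure: walking from a tip toward the root,
`ES = Σ l_j (1/2)^(j−1)` halves each successive edge's weight, so species in
clades that branch frequently near the present get small ES and large DR.
The halving is applied per node passed (the binary-tree rule; trees are
binary after imputation). Evolutionary time is measured by the tip age — the
pendant edge length, i.e. the time since the species' last splitting event.
A birth–death correction for unsampled speciation events is a documented
extension point; the uncorrected pendant age is what the package computes.

Taxa with distribution data but no phylogenetic data are added by
`impute_missing_taxa()`, a deliberately simple stochastic grafting scheme:
within the species' assigned clade (crown subtree plus stem edge) an
attachment edge is drawn proportionally to its length, the attachment time
is uniform along the edge, and the new pendant reaches exactly to the
present, so ultrametricity is preserved to machine precision. This mimics
the role of full taxonomic-addition samplers at a fraction of their
complexity; because the grafting is not birth–death weighted, attachment
times are biased toward long edges, which is acceptable here because
downstream metrics are averaged over many replicates and over the species in
a cell. The simplification is isolated behind this single function.
Averaging happens species-first: DR and tip age are averaged across the
replicate trees per species (`species_metrics_over_trees()`), then across the
species present in each cell (`cell_means()`), matching the stated order of
the workflow the package reproduces.

## Spatial statistics

`build_weights()` supports queen/rook contiguity, distance bands, and
symmetrized k-nearest neighbours, always row-standardized, with the binary
relation symmetric before standardization. Queen contiguity is the default
scheme; the original analysis defers its exact neighbourhood settings to
supplementary material, so the scheme is a configuration knob recorded in
the outputs rather than a hard-wired guess. Isolated cells are allowed but
reported. Eigenvalues of the row-standardized matrix are obtained from the
symmetric similarity transform `D^{-1/2} B D^{-1/2}` and cached on the
weights object, since both the SAR log-determinant and the admissible
interval for the spatial parameter derive from them.

**Dutilleul's modified t-test** corrects the correlation test between two
spatially autocorrelated fields by estimating each field's spatial
covariance matrix from distance classes (equal-width bins, Sturges' rule by
default; the diagonal forms its own class) and reducing the sample size to
the effective value `M̂ = 1 + tr(BΣ̂xBΣ̂y)^{-1} tr(BΣ̂x) tr(BΣ̂y)`. `M̂` is
capped at `n` (the moment estimator can exceed it by sampling noise) and an
`M̂ ≤ 2` outcome reports p = 1 with a warning. The test assumes isotropy and
second-order stationarity, as in the original method. `dutilleul_setup()`
precomputes the trace terms once per coordinate set, which makes the
simulation studies in the test suite cheap.

`collinearity_screen()` applies the |r| > 0.8 rule within declared pathway
groups, eliminating greedily: the member of the worst pair with the larger
mean absolute correlation to the remaining variables is dropped (the source
analysis does not state its tie-break; this one is deterministic and
documented). All pairwise results are reported whether or not anything is
dropped.

## The SAR error engine

Every structural equation is `y = Xβ + u`, `u = λWu + ε`. With
`A = I − λW`, profiling gives `β̂(λ)` and `σ̂²(λ) = e'e/n` from the
regression of `Ay` on `AX`, and
`ℓ(λ) = −(n/2)(log 2πσ̂² + 1) + Σ log|1 − λω_i|` is maximized by Brent
search (tolerance 1e-8) over `(1/ω_min + δ, 1/ω_max − δ)`, `δ = 1e-5`.
Estimates within 1e-6 of the boundary raise an error with diagnostics rather
than silently returning a degenerate fit. Standard errors use
`σ̂²[(AX)'(AX)]^{-1}`, the observed information for `β` at the optimum —
asymptotically orthogonal to `(λ, σ²)` and adequate for the screening-level
p-values consumed by the d-separation tests. The parameter count
`k = p + 2` includes the intercept, each slope, `λ` and `σ²`, and is stored
on the fit so alternative counting conventions can be audited. With an empty
neighbour structure the likelihood is flat in `λ` and the fit reduces
exactly to OLS with `λ = 0`.

The pseudo-R² is Nagelkerke's, `1 − exp((2/n)(ℓ_null − ℓ_model))`, with the
*intercept-plus-λ* model as the null. This is a conservative choice: the
spatial null can absorb smooth environmental signal, so these R² values are
lower than those produced against a non-spatial intercept-only null. Both
conventions exist in the literature; the spatial null is implemented because
it isolates what the predictors add beyond pure spatial autocorrelation.

## The pSEM engine

A `psem_spec()` is a DAG over standardized variables in which the response
(richness) is a pure sink; every variable with parents gets one SAR
equation. The default candidate generator crosses endogenous configurations
(speciation rate, evolutionary time, or both as mediators) with the role of
each exogenous variable — directly affecting the response, affecting a
mediator, or both — deduplicating the result. Because the 93-model list of
the original study is not reproduced in the available text, candidates are
configuration-driven rather than hard-coded.

Models are scored by the *sum of component AICc values* (likelihood-based
scoring). The alternative, Fisher's-C-based AIC, is undefined for saturated
models, yet a saturated model can legitimately win a likelihood-based
ranking — which is exactly the situation the package must be able to
represent; the d-separation output therefore reports the explicit marker
`"SATURATED"` (never a numeric 0) when the basis set is empty. One caveat is
inherent to summed scoring: totals are only comparable across models with
the same set of equations. `enumerate_candidates(require_mediated = TRUE)`
restricts the set accordingly (and the pipeline uses it), and
`rank_and_select()` warns when asked to compare heterogeneous sets.

d-separation claims follow Shipley's basis-set convention: one claim per
non-adjacent pair with at least one endogenous member (exogenous variables
are free to covary), conditioning on the union of both variables' parents,
testing the earlier variable's coefficient in the SAR regression of the
later one. `C = −2Σ log p` with `2k` degrees of freedom; zero p-values are
floored at 1e-300 with a warning. Ties in the AICc ranking are broken by
fewer parameters, then stable input order, and flagged.

Direct effects are the standardized coefficients of edges into the response;
indirect effects sum the coefficient products over all directed paths,
computed exactly via the nilpotent series `(I − B)^{-1} − I`; totals are
their sum. "Significance" of individual paths (for dashed-arrow style
reporting) uses the SAR coefficient p-value at α = 0.05, uncorrected,
matching the presentation style of the analyses this package reproduces.

## The synthetic-data generator

The generator exists so that every stage has a parameter-recovery surface
with known truth; its defaults are the package's declared study conditions,
not tuning knobs.

* **Trees** (`simulate_bd_tree()`): forward birth–death simulation from a
  two-lineage crown, stopped the moment the n-th extant lineage appears and
  extended by `u · Exp(n(b+d))`, `u ~ U(0,1)`, so pendant edges are strictly
  positive; extinct histories are rejected (cap 1000). This
  reject-and-retry scheme is simpler than exact conditioned samplers and
  adequate at the scale of a few hundred tips.
* **Fields** (`simulate_env_field()`): Gaussian-kernel smoothing of white
  noise with edge renormalization, standardized post hoc. Kernel smoothing
  was chosen over spectral methods: no extra dependencies and sufficient
  control of the autocorrelation range through the bandwidth.
* **Ranges** (`simulate_ranges()`): each species' environmental optimum
  evolves on the tree by unit-rate Brownian motion (only relative optima
  matter), and its range grows by spreading dye — repeatedly annexing the
  best-matching free rook-neighbour from the best-matching seed cell until a
  drawn (log-normal, ~5% of land cells) size is reached. Ranges are
  connected by construction; related species have similar optima and hence
  overlapping ranges.
* **Cell tables** (`simulate_structural_cell_table()`): exogenous layers are
  independent fields; each endogenous variable is a linear combination of
  its parents plus a SAR(λ) error generated exactly as `(I − λW)^{-1}ε`;
  the response adds direct and mediated effects plus its own SAR error.
  Innovation standard deviations are rescaled by the mean SAR inflation
  factor so variables keep variance near 1 and the generating coefficients
  read as standardized effects; coefficient recovery is unbiased regardless
  of this scaling. Grids are capped at desk scale so dense linear algebra
  suffices throughout.

A single master seed spawns labelled substreams per component, so trees,
fields, ranges and errors can be regenerated independently.

What the generator does *not* emulate: real paleogeography, geographically
structured speciation/extinction, range cohesion beyond rook connectivity,
observation error in range atlases, and non-stationary or anisotropic
environmental structure. Passing recovery tests therefore demonstrates the
estimators' correctness under the stated model, not robustness to every
failure mode of empirical range and climate data.

## Problem sizes and numerical choices

The recovery studies shipped with the package use sizes chosen to make their
Monte-Carlo error small relative to the tolerances they check while staying
desk-scale: SAR recovery on a 20×20 grid (β = (0.5, −0.3), λ = 0.6, 200
replicates), Dutilleul calibration at n = 400 with 1000 simulated field
pairs, pSEM recovery on a 30×30 grid (n = 900, direct effects 0.36/0.18,
mediated 0.10, λ = 0.5, 100 replicates, 10 candidate models), d-separation
calibration with 200 replicates at n = 400, and 100 imputation replicates.
Deterministic pieces (profile optimization, eigenvalues, path algebra) are
checked against brute-force oracles at 1e-8 to 1e-12.

Degenerate inputs are handled explicitly rather than silently: constant
variables abort normalization by name, zero-variance vectors abort Moran's
I, empty cells become missing values excluded from modelling, oversized
ranges truncate with a warning, orphaned species abort imputation with a
list of names, and boundary SAR estimates abort with diagnostics.

## Known limitations

* The imputation is not a birth–death-weighted taxonomic-addition sampler;
  attachment-time distributions differ from TACT's in the tails.
* Tip ages carry no correction for incomplete lineage sampling.
* The Dutilleul covariance estimator assumes isotropy; anisotropic fields
  shrink `M̂` imperfectly.
* Summed-AICc comparison requires a common equation set across candidates
  (enforced in the pipeline, warned about elsewhere).
* SAR variants beyond the error model (lag, Durbin), sparse log-determinant
  approximations, and bootstrap confidence intervals for standardized
  effects are out of scope.
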