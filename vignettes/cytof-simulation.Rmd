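---
title: "Simulating CyTOF data with cytosim: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating CyTOF data with cytosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytosim)
library(dplyr)
```

## The generative model

Mass cytometry (CyTOF) measures 30–40 metal-tagged protein markers on tens of
thousands to millions of single cells. After the standard preprocessing chain
(bead normalization and the `arcsinh(x/5)` transform), per-cell-type marker
distributions are near-Gaussian but frequently multimodal and zero-inflated,
and markers are correlated with one another. cytosim models a dataset of `P`
cell types on `M` channels as follows. Each cell draws a type from a
categorical distribution with abundance vector `pi`; given its type `p`, its
latent expression vector comes from a Gaussian mixture
`X ~ sum_k w_k N(mu_k^p, Sigma_k^p)`. The observed expressions are

```
Z = X + g(T) + psi_b + Psi_{b,p} + Phi_b(t_acq)
Y = max(Z, 0) + E
```

where `g(T)` is an optional differentiation shift at Beta-distributed
pseudotime `T`, `psi_b + Psi_{b,p}` an optional batch effect, `Phi_b` an
optional within-run signal drift evaluated at the cell's relative acquisition
time, and `E` zero-mean machine noise. Truncation at zero is element-wise
clipping — an exact reading of the indicator form of the model — rather than
rejection sampling from a renormalized density; noise added afterwards can
re-introduce small negative values, which mirrors the data randomization step
of real acquisition software.

Two modes produce the mixture parameters:

* **Creation mode** (`create_model()`, `generate_cell_type_params()`) draws
  them from user settings alone. Each type receives a random on/off pattern
  over channels; "on" channels draw their mean from a zero-truncated normal
  around `on_level_mean`, "off" channels sit near zero so that truncation
  produces the observed zero-inflation. Covariances are random PSD matrices
  `s^2 (A A'/M + 0.1 I)`. Nothing in the literature pins down a functional
  form for "degrees of heterogeneity", so this mapping — expression fraction
  plus level scales — is a documented package choice, not an estimated one.
* **Emulation mode** (`fit_reference()`) learns them from a labeled reference
  matrix: one EM fit per cell type for every component count between
  `min_components` and `max_components` (default 1–9), keeping the count
  that minimizes `BIC = -2 logL + k log n`. The per-type BIC curve is kept on
  the fitted object for inspection. Cell typing itself is deliberately out of
  scope: users bring their own labels.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `on_level_mean`, `on_level_sd` | 3, 1 | arcsinh units; expressed CyTOF markers typically sit around 2–5 |
| `off_level_sd` | 0.2 | near-zero location scale for unexpressed markers |
| `covariance_scale` | 0.3 | implied per-channel sd of a type |
| `component_spread` | 1 | sd of component-mean jitter; controls intra-type mode separation |
| `dirichlet_alpha` | 0.1 | skewed abundances typical of immune panels |
| `noise_sd` | 0 (emulation), 0.1 (creation) | machine noise; reference data already carries its own noise |
| `near_zero_threshold` | 1e-6 | what counts as "zero" for zero-inflation matching |
| `stay_prob` | 0.5 | probability a cell is not mid-differentiation |
| `beta_alpha`, `beta_beta` | 0.4, 0.4 | U-shaped pseudotime: cells concentrate at type endpoints |
| `change_frac` | 0.1 | channels below this fraction of the top shift stay flat along an edge |

The machine-noise family is not prescribed by the model (it is "some error
distribution"); we default to a zero-mean Gaussian with configurable sd, with
a mean-zero uniform available, because the symmetric randomization applied by
acquisition software is well approximated by either.

## Batch, temporal, and trajectory components

**Batch effects** decompose ANOVA-style into a global per-batch scalar
`psi_b ~ N(0, sigma_psi^2)` and type-by-channel interactions
`Psi_{b,p} ~ N(psi_b 1, sigma^2 I)`. Identifiability requires
`sum_b psi_b = 0`, `sum_p Psi_m = 0`, and `sum_m Psi_m = 0`; unconstrained
draws are projected onto the constraint space by (double-)centering, which is
the minimum-norm projection. Because the interaction slice is fully centered,
the batch-level mean shift is carried by `psi_b` alone, and the effect applied
to a cell is `psi_b + Psi_{b,p}` — the main-plus-interaction reading of the
decomposition. With a single cell type the centering forces `Psi` to zero
identically, so all batch separation then comes from `psi_b`.

**Temporal effects** are functions on `[0, 1]` with `f(0) = 0` (no drift at
the start of a run), evaluated at each cell's relative acquisition index
`n / N_b`; cells within a batch are emitted in acquisition order so the drift
is monotone in row order. Three generators are provided: a Brownian bridge
to a random `N(0, end_sd^2)` endpoint interpolated with an Akima spline
(default 6 interior knots — smooth, slow drift), a polynomial shape linearly
rescaled to the anchors, and a smoothing spline replaying residuals the user
extracted from their own data (times are rescaled to the unit interval and
the curve re-anchored at zero). The drift is a single scalar function per
batch broadcast across channels, matching the observation that within-batch
drift is shared across cell types; independent per-channel functions can be
built by passing one temporal object per batch and channel group if needed.

**Trajectories** live on a polyforest over the cell types. Creation mode
partitions types randomly into `n_trees` groups and takes a minimum spanning
tree over i.i.d. Uniform(0,1) weights within each group; emulation mode
weights the complete graph with L2 distances between fitted type means,
partitions it with Clauset–Newman–Moore greedy modularity, and takes the MST
within each community. (We pass the distance weights to the modularity step
exactly as the procedure prescribes, although distances are an unusual
affinity; with two types the partition is forced to a single community since
modularity on a two-node graph degenerates to singletons.) A DFS from a
random root orients each component. Along an edge, each changing channel
follows `g_m(t) = t * delta_m + B_t - t B_1` — a Brownian bridge from 0 to
the parent-to-child mean difference — interpolated with a natural cubic
spline; channels whose shift is below `change_frac` of the edge's largest
shift stay flat, which keeps lineage-irrelevant markers stable. One
pseudotime per cell is applied to all channels (a per-channel pseudotime
would decouple a cell's markers mid-edge, which has no biological reading).
The Beta pseudotime parameters may vary by batch.

## Zero-inflation matching

A fitted mixture can under-produce near-zero values relative to its
reference. For each channel whose simulated near-zero fraction `q` falls
short of the observed fraction `q*`, cells above the threshold are set to
exactly 0 with probability inversely proportional to their magnitude, capped
at 1 and rescaled so the expected number of new zeros equals `(q* - q) n`.
Matching runs on the latent per-type draws *before* effects are added, so
targets keep their meaning regardless of which effects are enabled. Whether
matched values should be exactly zero or merely near zero is ambiguous; we
set exactly 0 and count `|x| <= near_zero_threshold` as "near zero" on both
sides, which makes the calibration self-consistent.

## Evaluation metrics

`evaluate_simulation()` scores a simulation against a reference per cell
type and aggregates with abundance weights: L2 distance of mean vectors,
Frobenius distance of covariance matrices, a k-nearest-neighbour estimate of
the KL divergence (`k = 1`, Euclidean metric, self-match excluded; the
estimator can be slightly negative at small `n` and is reported as-is), and
the propensity score mean squared error (pMSE) from a logistic model with a
permanent ridge of `1e-6`. The default propensity terms are main effects
plus squares and pairwise interactions: with per-type means matched (which
any reasonable fit achieves), a main-effects-only logit is blind to exactly
the covariance and modality structure the metric is meant to probe, so the
quadratic expansion is what makes pMSE informative here; `terms = "main"`
restores the plain main-effects model. The analytic null level of pMSE is
`k c (1 - c) / N` with `k = pmse_n_predictors(M)` fitted coefficients.
`relative_efficiency()` expresses competing pMSE values as a ratio to the
reference method's; the reference versus itself is exactly 1.

## Numerical choices and degenerate inputs

* EM initialization uses mclust's model-based hierarchical agglomeration on
  a seeded subsample of at most `init_subset = 2000` cells: deterministic
  under a fixed seed and robust, making random restarts unnecessary. Rows
  are put into a canonical sort order before fitting so results are
  invariant to how the caller ordered the cells.
* Covariances failing Cholesky get `1e-6 I` jitter with a warning; constant
  matrices are jittered (`sd 1e-6`) and refit once.
* Types with fewer cells than `max_components + 1` shrink the component
  range with a warning; types with fewer than 2 cells are dropped with a
  warning naming them.
* All sampling flows from one root seed through deterministic per-(module,
  batch) child streams (`derive_seed()`), so enabling one effect never
  perturbs draws of another, and a `(config, seed)` pair reproduces outputs
  byte-for-byte.

## What the synthetic generator does and does not cover

The built-in generators (`create_model()`, `generate_fixture()`) reproduce
zero-inflation, marker correlation, multimodality, batch/temporal structure,
and lineage interpolation — the features the model is built around. They do
not emulate spillover, raw ion-count statistics, bead-normalization
artifacts, any specific antibody panel, or the label noise of real cell
typing. Tests passing on these fixtures therefore demonstrate internal
correctness and recoverability, not that any particular real cohort is
matched; for that, emulation mode should be run on the cohort itself.

Problem sizes in the test-suite and acceptance runs — e.g. 3 types x 3
components x 10 channels at 20000 cells per type for recovery, 20000-point
samples for the KL oracle, 10000 cells for zero-matching calibration — were
chosen as the smallest sizes at which the asymptotic properties under test
(BIC consistency, estimator convergence, calibration in expectation) are
comfortably in force.

## A worked example

```{r example, eval = FALSE}
model <- create_model(n_types = 5, n_channels = 30, n_components = 2, seed = 1)
trajectory <- build_trajectory(model, n_trees = 2, seed = 1)
effects <- batch_effects(2, 5, 30, sigma_psi = 0.1, sigma = 0.1, seed = 1)

sim <- simulate_cells(model, c(5000, 5000), batch_effects = effects,
                      trajectory = trajectory, noise = 0.1, seed = 1)
autoplot(sim)

refit <- fit_reference(sim, seed = 2)
evaluate_simulation(simulate_cells(refit, 10000, seed = 3), sim)
```

## Known limitations

Per-type EM can be unstable for very rare cell types (no strength is
borrowed across types); moments, zero-inflation, and trajectories are fitted
or applied sequentially rather than jointly, so estimated parameters carry
some bias by construction; converging or cyclic lineages are out of scope
(the trajectory graph is a polyforest by design); and FCS files are not read
directly — export to CSV/TSV first (an `asinh(x/5)` flag is available for
raw-scale tables).
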