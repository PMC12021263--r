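---
title: "Trait-scapes, clustering and plasticity metrics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-scapes, clustering and plasticity metrics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, and the choices made where the underlying
procedure is genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The measurement model

The unit of observation is one batch culture: a species grown at one
salinity in one replicate flask, monitored by chlorophyll-a fluorescence
(a biomass proxy) and harvested once for cell density, pigment,
particulate C/N/P, residual dissolved nutrients (NOx, NH4, PO4, Si) and
total N/P pools. Canonical internal units are umol L^-1 for dissolved
concentrations, ug L^-1 for particulate ones, cells L^-1 for densities and
days for time: with those, the batch drawdown rate comes out directly in
umol cell^-1 day^-1.

### Growth rate

`mu = (ln F2 - ln F1)/(t2 - t1)` over the exponential phase of the
fluorescence series. How the endpoints of the exponential phase are chosen
is an open methodological point in gradient experiments; the package's
default (`exp_phase_method = "max_slope"`) is an objective rule: among all
contiguous windows of at least `exp_phase_window = 2` positive-fluorescence
points, take the one with the steepest least-squares slope of log
fluorescence against day; ties within a relative 1e-9 go to the longest
window, then the earliest start. On a clean exponential segment this
recovers the true rate exactly; on lag-rise-plateau series it isolates the
rise. An `"endpoints"` mode (first/last observation) is available for
comparison. A series that never shows a positive-slope window yields
exactly `mu = 0` — non-growth is a value, not a missing datum.

### Uptake, quotas, ratios, RUE

Net uptake is the bulk budget `S = (N_t0 - N_t1)/(C * dt)`; it is a *net*
drawdown rate, not a kinetic parameter (no Michaelis–Menten fitting).
Negative drawdown — release, remineralization, or analytical noise — is
clamped to exactly 0, and the row is flagged so the clamp is auditable.
Quotas are bulk concentration over final cell density; C:N:P ratios are
molar (atomic masses 12.011, 14.007, 30.974). Resource use efficiency is
`log10(POC_molar / TN)` and `log10(POC_molar / TP)`: the log base and the
molar-vs-mass convention differ across the limnological literature, so
both are configurable (`trait_spec(log_base =, rue_unit_mode =)`); base-10
molar is the default because unqualified "log" in RUE work is most often
log10, and molar ratios keep RUE commensurate with the stoichiometric
traits.

### Dead cultures

A culture with zero final cell density (no live cells at harvest) gets
growth rate, quotas and uptake rates of exactly 0 and a `dead_culture`
flag, rather than missing values. This keeps the trait matrix row-complete
for the ordination — a multivariate method cannot use an NA — while the
flag lets any downstream analysis exclude those rows
(`plasticity_metrics(..., drop_rows = )`). Ratio and RUE traits remain
defined when the particulate pools are positive (dead cells still carry
C, N and P); where they are not, the entry is 0 and flagged.

## 2. Trait-scapes

Traits mix units (day^-1, ug cell^-1, dimensionless logs), so the PCA is
correlation-based: each column is centered and scaled to unit standard
deviation (n−1 denominator), and components are eigenvectors of the
correlation matrix. The implementation uses the singular value
decomposition of the standardized matrix for numerical stability; the test
suite cross-checks it against a direct eigendecomposition. Component signs
are fixed by making the largest-magnitude loading of each column positive,
so repeated fits are bit-identical. Total variance equals the number of
traits, and explained-variance fractions always sum to 1.

The **basal trait-scape** is fitted on the maintenance-salinity subset
(default 5 psu) only: interspecific trait structure under the conditions
the strains were kept in. The **extended trait-scape** pools all
salinities, so treatment effects and species differences share one score
space. Replicates enter as individual rows in both. Any cell-size column
(`cell_size`, `cell_volume`, `biovolume`) is excluded from the ordination
with a logged notice: when species are deliberately chosen to span a wide
size range, size would dominate the first component and inflate
collinearity with the allometrically-scaled traits. `project_traitscape()`
places new rows into a fitted scape using its stored means and scales.

All components are retained by default; downstream stages choose how many
to consume. The biplot plane (PC1–PC2) is the default for the distance
metrics because it is the space actually interpreted, but every metric
accepts `n_dims = "all"`.

## 3. Clustering on principal components

Ward's minimum-variance criterion on the PC scores, implemented directly
via Lance–Williams updates with two contract-level details that generic
implementations do not pin down:

- **Heights are ΔSS** — the increase in within-cluster sum of squares at
  each merge — not a rescaled distance. This makes the merge heights the
  same currency as the between-inertia gains used to suggest the cluster
  count (`stats::hclust(method = "ward.D2")` heights are `sqrt(2 ΔSS)`;
  the test suite verifies that correspondence).
- **Deterministic tie-breaks**: equal-cost merges are resolved by the
  smallest, then second-smallest, original row index in the candidate
  pair, so permuting the input changes labels only.

`suggest_k()` maximizes the ratio of successive between-inertia gains
Δ(k)/Δ(k+1) — the conventional elbow rule for clustering on principal
components — and is always user-overridable, because no automatic rule is
authoritative at n = 10 species. An optional consolidation step
(`consolidate()`) reassigns rows to nearest centroids until stable; it
never increases within-cluster sum of squares but is off by default so the
reported partition is exactly the tree cut. Clustering defaults to group
centroids (species, or species-by-salinity treatments) rather than
replicates, matching how such groupings are usually displayed and
interpreted; `level = "replicate"` is available. Cluster descriptions rank
traits by the standardized deviation of the cluster mean from the grand
mean.

## 4. Plasticity and variability metrics

Both metrics are mean Euclidean centroid distances in score space:

- **Species plasticity**: mean distance of a species' replicate positions
  (all salinities pooled) from the species centroid.
- **Interspecific variability per salinity**: distances from the salinity
  centroid. Two variants exist because the species-centroid-based and the
  replicate-based version answer slightly different questions; the default
  is `replicate_based` (every flask counts), and the variant used is
  recorded in the result.

Distances are unweighted across components — correlation-PCA scores are
already variance-scaled — and are computed on `n_dims = 2` by default. The
one-way ANOVA compares replicate-to-salinity-centroid distances across
salinity levels (a single test; no multiplicity correction). Exact
geometric properties hold by construction and are enforced by tests:
rigid-motion invariance, exact linear scaling of plasticity when replicate
scatter is inflated about centroids, and zero plasticity iff a species'
replicates coincide.

## 5. The synthetic generator

The generator emulates the statistical structure the analysis assumes,
with every latent value recorded for recovery tests:

- **Reaction norm**: Gaussian in salinity,
  `mu(s) = mu_max exp(-(s - s_opt)^2 / (2 s_tol^2))`, floored to 0 below
  5% of `mu_max` (far-off-optimum conditions are lethal, not slow). A
  Gaussian is the minimal unimodal choice for a tolerance curve.
- **Allometry**: quotas scale with cell volume as `(V/100 um^3)^0.9`;
  baseline carbon quota 2e-5 ug C/cell at 100 um^3 (~0.2 pg C um^-3);
  N and P quotas follow Redfield proportions from the carbon quota.
- **Batch dynamics**: exponential growth after a 1-day lag, capped when
  the cumulative N or P demand of new cells exhausts the medium; the
  treatment ends at the first monitoring day in stationary phase, after
  three growth-free monitoring days (day 6) for non-growing cultures, or
  at day 20. Residuals are exact mass balances (initial − new cells ×
  quota), so applying the drawdown formula to a noiseless record recovers
  the generator's own uptake to machine precision.
- **Plasticity signal**: quotas are multiplied by
  `1 + plasticity_amp * tanh(|s - s_opt| / s_tol)`, with the sign of the
  shift drawn once per trait per species from the experiment seed. Signs
  matter: a species whose C and N shifts are aligned shows little C:N
  response, one with opposed signs a strong one — the amplitude-to-
  displacement mapping is deliberately heterogeneous, as it is in real
  taxa.
- **Totals**: TN = (inorganic N + particulate N)/(1 − 0.05), i.e. a 5%
  dissolved-organic fraction, so total pools always exceed their parts.
  Totals are computed from the *noisy* component pools, keeping
  TN ≥ inorganic N even under measurement noise.
- **Noise**: every observable is multiplied by lognormal noise with mean 1
  and CV `noise_cv` (default 10%); replicates are i.i.d. (no flask random
  effect). All randomness flows from one seed; identical seeds give
  bit-identical experiments.

The default community (`default_species_params()`) caricatures a brackish
culture collection: ten species spanning ~5 um^3 to ~10^5 um^3, growth
optima mostly at 2–15 psu, one broadly euryhaline diatom
(`s_tol = 30 psu`, lowest amplitude) and narrower specialists with
amplitudes up to 0.2. It is illustrative — end-to-end runs reproduce the
qualitative patterns expected of such a community — not an inference about
any particular strain.

What the generator does *not* emulate: osmoregulatory mechanism,
time-resolved nutrient kinetics, inter-species competition, flask random
effects, or non-Gaussian (e.g. flat-topped) tolerance curves beyond what
`s_tol` can mimic. Passing tests therefore demonstrate correctness of the
*computations* and recoverability of *planted* structure, not that real
communities behave this way.

## 6. The parameter-recovery study

The recovery check asks: if ten species differ only in their plasticity
amplitude (4-fold range), does estimated species plasticity rank them
correctly at 10% measurement noise? The fixture uses amplitudes 0.25–1.0
(quota shifts up to ~75% at saturating stress, within the range reported
for elemental-content change under osmotic stress), a sublethal gradient
(`s_tol = 25 psu`, since plasticity is biologically expressed under
sublethal, not lethal, stress — lethal levels collapse all traits to the
dead-culture signature and mask the signal), and distances in the full
score space, which is rotation-equivalent to the standardized trait space.
Because the per-species sign draws make the amplitude-to-displacement
mapping heterogeneous (Section 5), the rank correlation has a ceiling
below 1 even without noise; the test requires a median Spearman ≥ 0.8
over 20 seeded studies, which the suite computes each run.

## 7. Problem sizes, tolerances, and degenerate inputs

- Test and acceptance runs use the default 10 × 6 × 3 design (180
  cultures, ~11 monitoring points each); PCA oracle checks use 50 random
  30 × 15 matrices; Ward oracle checks use 100 instances of ≤ 8 points in
  ≤ 3 dimensions, where exhaustive greedy search is feasible.
- Numerical tolerances: eigenstructure to 1e-8 against the independent
  decomposition; exact-arithmetic identities (hand-computed trait rows,
  distance oracles) to 1e-10; conservation laws (variance totals, inertia
  decomposition, mass balance) to 1e-9; file round-trips to 1e-12
  relative (tables are written with 15 significant digits).
- Degenerate inputs fail loudly and early: zero-variance trait columns
  name the trait; series shorter than the minimum window, empty point
  sets, out-of-range k, and degenerate ANOVA degrees of freedom are
  errors, not warnings. Zero-clamped values are exactly 0, never tiny
  negatives.

## 8. Known limitations

- The exponential-phase window rule is a reproducible stand-in, not a
  reconstruction of any particular laboratory's judgment; on noisy,
  short series the two can differ.
- The suggested cluster count is a heuristic; at 10 species the
  between-inertia ratio can be nearly flat across k, and the user should
  inspect `inertia_gains()` rather than trust the argmax.
- NOx uptake treats NO3 + NO2 as one pool and ignores NH4 released by the
  cultures; strongly ammonium-regenerating cultures will show biased net
  uptake.
- Plasticity on two components measures movement in the interpreted
  plane only; species whose salinity response is orthogonal to PC1–PC2
  need `n_dims = "all"`.
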