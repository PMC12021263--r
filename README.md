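# traitscape

Trait-based analysis of phytoplankton salinity responses: from raw
batch-culture measurements to a physiological trait matrix, principal
component "trait-scapes", Ward clustering of the reduced space, and
centroid-distance metrics of trait plasticity.

## The problem

Estuarine and brackish-sea phytoplankton experience strong salinity
fluctuations, and a freshening trend threatens to filter species out of
such communities. A standard way to ask *which* species cope, and *how*, is
a mono-algal gradient experiment: grow each species at several salinities
with replicate flasks, monitor growth by chlorophyll-a fluorescence, and
harvest each culture for cell density, pigment, particulate C/N/P, and
residual dissolved nutrients. This package turns such a table of
measurements into a multivariate answer. It is aimed at experimental
plankton ecologists who want the full chain — trait derivation, ordination,
clustering, plasticity metrics — reproducible from one seed and one
configuration file.

## The method

From each replicate culture, 15 physiological traits are derived:

- **Specific growth rate** over the exponential phase of the fluorescence
  series, `mu = (ln F2 - ln F1) / (t2 - t1)`; cultures that never show
  increased fluorescence get exactly `mu = 0`.
- **Net nutrient uptake rates** from batch drawdown,
  `S = (N_t0 - N_t1) / (C * dt)` with `N_t0` the medium concentration
  (F/2: NO3 882, PO4 36, Si 106 umol/L), `N_t1` the residual at harvest,
  `C` the final cell density and `dt` the incubation length; negative
  drawdown is clamped to 0.
- **Per-cell quotas** (chl-a, C, N, P) as bulk concentration / cell
  density, and the molar **C:N, C:P, N:P** ratios.
- **Resource use efficiencies** `RUE_N = log10(POC / TN)` and
  `RUE_P = log10(POC / TP)` on molar concentrations.
- Bulk **POC**, **cell density** and **chl-a** as realized-biomass traits.

The trait matrix is standardized and ordinated by correlation PCA. The
**basal trait-scape** uses only the maintenance-salinity (5 psu) rows —
interspecific variability before treatment; the **extended trait-scape**
pools all salinities. Ward's minimum-variance clustering on the PC scores
(hierarchical clustering on principal components) groups species or
species-by-salinity treatments, with the cluster count suggested by the
ratio of successive between-inertia gains. Two centroid-distance statistics
summarize the score space: **species plasticity** (mean distance of a
species' replicate positions from its centroid, salinities pooled) and
**interspecific variability per salinity** (mean distance from the salinity
centroid), compared across salinities by one-way ANOVA.

A synthetic-data generator emulates the whole 10-species x 6-salinity x
3-replicate experiment — Gaussian salinity reaction norms, allometric quota
scaling with cell volume, nutrient-exhaustion growth caps with an exact
mass balance, salinity-stress quota shifts, and lognormal replicate noise —
so the pipeline runs end-to-end with known ground truth.

## Worked example

```r
library(traitscape)

sim <- generate_experiment(synthetic_config(seed = 7))
tm  <- build_trait_matrix(sim$records)

basal    <- basal_traitscape(tm)       # 5 psu rows only
extended <- extended_traitscape(tm)    # all salinities pooled
print(basal)
#> traitscape: 30 rows x 15 traits, 15 components retained
#> PC1 59.9%, PC2 14.6% of total trait variance

clusters <- cluster_traitscape(extended, level = "centroid",
                               group = "treatment", tm = tm)
print(clusters)
#> cluster_solution: 60 centroids in 3 clusters (Ward on PC scores)
#> cluster
#>  1  2  3
#> 25 29  6

pl <- plasticity_metrics(extended)
print(pl)
#> plasticity_result (2 PC dims, replicate_based salinity metric)
#> species plasticity:
#>    chlorophyte_freshwater      cryptophyte_brackish        cryptophyte_marine
#>                     2.353                     1.962                     1.781
#>        diatom_stenohaline    dinoflagellate_benthic      dinoflagellate_large
#>                     1.689                     1.404                     1.127
#>  dinoflagellate_mixotroph          haptophyte_small pennate_diatom_euryhaline
#>                     1.318                     2.135                     0.364
#>        picocyanobacterium
#>                     2.346
#> interspecific variability per salinity:
#>     0     5    15    20    30    35
#> 2.385 1.530 2.349 2.677 2.047 2.205
#> ANOVA across salinity: SS = 22.7, F = 1.538, p = 0.18
```

Reading the output: the first two basal PCs carry ~75% of the trait
variance, so the biplot plane is a faithful summary of interspecific
differences at the maintenance salinity. The treatment centroids fall into
3 clusters. The broadly euryhaline pennate diatom has by far the lowest
plasticity (0.36) — its trait expression barely moves along the gradient —
while narrow-tolerance species that still survive off-optimum score
highest. The ANOVA finds no significant difference in interspecific
variability among salinity levels (F = 1.54, p = 0.18).

One call runs everything and writes every artifact (CSV tables, optional
figures, a hash manifest) under a directory:

```r
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 7))
```

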