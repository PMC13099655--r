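# spatialbreast

Spatial single-cell analysis of multiplexed (imaging mass cytometry, IMC)
images of normal breast tissue across the adult lifespan. The package
implements, as a tested reusable pipeline, the stages needed to go from
pixel-level marker signal to cohort-level nonlinear aging statistics:

* **Pixels** — hot-pixel filtering; k-means marker positivity masks;
  morphological adipocyte detection (Otsu + inversion + 300 µm² /
  circularity ≥ 0.7 filters with panCK subtraction); myoepithelial-layer
  thickness by distance transform; vessel-mask metrics.
* **Cells** — 99th-centile clip + min–max expression scaling,
  PhenoGraph-style shared-nearest-neighbour clustering of a subsample,
  random-forest label propagation, and size/cell-count QC.
* **Architecture** — Delaunay cell–cell graphs pruned at 20 µm,
  normalized interaction rates, nearest-epithelium distances, bivariate
  Ripley's K with 199-simulation CSR envelopes, CellCharter-style
  3-hop neighbourhood aggregation + Gaussian-mixture niche clustering with
  Fowlkes–Mallows stability selection, connected-component communities
  (≥ 10 cells) with Shannon diversity and mean degree, and duct/lobule
  structure graphs with 3-hop microenvironment association.
* **Cohort statistics** — convex-hull tissue areas and pooled patient
  densities; Spearman age associations; age-50 group comparisons with
  Mann–Whitney tests, Benjamini–Hochberg correction and Cliff's delta
  (with consistent-variance CIs); paired duct-vs-lobule composition
  tests; core-to-core variability; DE-SWAN-style sliding-window "aging
  wave" counts; quadratic-spline-vs-linear likelihood-ratio tests for a
  menopause step; and crop/sample-size sensitivity analyses (KL
  divergence, co-occurrence cosine similarity).

Because the motivating cohort data are external, the package ships a
**synthetic tissue generator** (`cohort_config()`, `generate_cohort()`,
`generate_image()`) that emulates the statistical structure of an aging
breast cohort — duct/lobule/adipocyte/vessel architecture, exponential
density declines, a declining Ki67⁺ fraction, a lobule-density step at
age 50, growing adipocyte area — with complete ground truth, so every
stage is testable end to end.

## Worked example

```r
library(spatialbreast)

cfg <- cohort_config(n_patients = 100, seed = 101)
co  <- generate_cohort(cfg)
co
#> tissue_cohort: 100 patients, 145 images, 64077 cells
#>   ages 21-79 (median 38)

fm <- build_feature_matrix(co)
fm
#> feature_matrix: 100 patients x 39 features

spearman_age(fm$features[, "density_epithelial"], fm$ages)
#> $rho
#> [1] -0.542
#> $p
#> [1] 5.98e-09
```

The negative Spearman coefficient recovers the programmed exponential
decline of epithelial density with age (the generator's
`density_decline_rate`), estimated entirely through the pipeline: hull
areas, pooled per-patient densities, rank correlation. The same matrix
feeds the age-group effect-size panel and the sliding-window analysis:

```r
cmp <- age_group_compare(fm$features[, c("density_epithelial",
                                         "density_stromal",
                                         "density_immune")], fm$ages)
cmp[, c("feature", "delta", "q")]
#>              feature     delta            q
#> 1 density_epithelial 0.8387534 4.305928e-08
#> 2    density_stromal 0.9634146 5.504339e-10
#> 3     density_immune 0.7953930 1.424599e-07
```

The delta column is Cliff's delta for young (< 50) versus old (≥ 50)
patients: values near +1 say a randomly chosen younger patient almost
always has the higher density — the programmed decline, in all three
compartments.

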