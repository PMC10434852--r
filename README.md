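# optihab

Mapping small-mammal optimal habitat from satellite-derived landscape proxy
variables and field surveys, with random-forest species distribution models
(SDMs).

Small mammal populations — voles, mole-voles, shrews — drive grassland
dynamics, agricultural damage and the transmission of rodent-borne
parasites. Where a species can reach outbreak densities depends on habitat
composition and vegetation dynamics that field surveys alone cannot map.
`optihab` is an R implementation of the full analysis chain that links the
two data worlds, aimed at landscape ecologists and disease-ecology
modellers:

1. **EO proxy variables.** Spectral vegetation/water indices (NDVI, NDWI,
   MNDWI, EVI, GRVI, DVI, TVI, SVVI, SAVI, tasselled-cap brightness/
   greenness/wetness) are computed per cloud-masked scene and collapsed
   over the acquisition period into per-pixel percentile metrics
   (p5-p95, range, r75-25, r90-10, r95-5), capturing phenological dynamics
   detached from event timing. A 200-tree random-forest land-cover
   classification (8 classes) feeds focal habitat proportions in nested
   50-500 m kernels; SRTM-style terrain adds elevation, slope, aspect.
2. **Abundance indices.** Trapline captures (25 break-back traps x 3
   nights) are modelled as
   `log E[c] = β₀ + β_type·I[bbbt] + β_night·(night−1) + u_line + log(accessible)`
   (Poisson GLMM with trapping-effort offset); where trap type or control
   night matters, per-line mean residuals become the species' relative
   abundance index, otherwise captures per 100 trap-nights. Transect scores
   count activity-positive intervals (0-20). Moran's I and empirical
   semivariograms check the no-spatial-autocorrelation assumption.
3. **Selection and SDM.** An all-relevant Boruta-style shadow-feature
   selection (binomial hit tests against the maximum shadow importance,
   Bonferroni α = 0.01) retains the statistically important covariates. A
   random-forest regression with tuned hyperparameters (trees, minimum
   leaf, node cap, variables per split, bag fraction) is validated by
   leave-one-out cross validation (R² = 1 − SSE/SST) and applied
   predictively; pixels whose predicted abundance exceeds the **mean
   predicted abundance of the training data** are classified optimal, and
   optimal area (km², % of land) is reported per species.

Because the real inputs of such studies (Landsat surface reflectance,
survey tables) are rarely shareable, the package includes a first-class
synthetic-data generator — seasonal per-class reflectance with coherent
cloud gaps, a class-correlated DEM, and Poisson/Bernoulli surveys driven by
a known function of the EO covariates — so every stage is testable against
known ground truth.

## Worked example

The demo scenario: a 160 × 160 pixel (4.8 × 4.8 km, 30 m) mountain
landscape, 12 scene acquisitions at 25% cloud, 60 traplines and 40
transects for two species whose true dependence on the landscape is known.

```r
library(optihab)
res <- run_pipeline(demo_config(seed = 1))
print(res)
#> <pipeline_result> 2 species, land-cover accuracy 1.000
#>   grassland_vole (trapline): LOOCV R2 0.802, threshold 37.122, optimal 38.3%
#>   mole_vole (transect): LOOCV R2 0.673, threshold 6.525, optimal 35.7%
```

Reading the output: the synthetic land cover is recovered perfectly at this
noise level (real studies report 85-95%); leave-one-out R² of the two SDMs
(0.80 trapline, 0.67 transect — transect scores carry irreducible
Binomial(20) noise); the mean-training-prediction threshold per species
(in index units: GLMM-residual units for the trapline species, interval
counts for the transect species); and the share of land classified optimal.
The Spearman correlation between the predicted surface and the true latent
abundance is ~0.9 for the trapline species
(`cor(as.vector(res$sdm$grassland_vole$prediction), as.vector(res$sdm$grassland_vole$truth_abundance), method = "spearman", use = "complete.obs")`).

The same analysis, stage by stage with tables and rasters written under
`results/`, is laid out in numbered scripts:

```sh
Rscript analysis/01_simulate_landscape.R      # landscape + scene collection
Rscript analysis/02_eo_metrics.R              # indices + percentile metrics
Rscript analysis/03_landcover_classification.R
Rscript analysis/04_survey_abundance.R        # GLMM indices, Moran's I
Rscript analysis/05_feature_selection.R       # Boruta + importance ranking
Rscript analysis/06_sdm_mapping.R             # tune, LOOCV, predict, threshold
```

Key outputs: `results/loocv_validation.csv` (species × method × R²),
`results/optimal_habitat_areas.csv` (threshold, optimal km², % total land),
`results/boruta_selection.json`, `results/autocorrelation.json`, and
prediction/optimal-habitat rasters as TIFF with JSON grid sidecars.

## Scope

No atmospheric correction, gap-filling, occupancy modelling,
capture-recapture estimators, MaxEnt, prediction intervals, or population-
cycle dynamics. Rasters are in-memory matrices on a metric grid with
lightweight TIFF+JSON interchange — not a GIS.
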