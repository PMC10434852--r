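---
title: "Methods: satellite proxy variables and random-forest SDMs for small mammal habitat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite proxy variables and random-forest SDMs for small mammal habitat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

optihab implements a complete workflow for mapping the optimal habitat of
small mammal species from Earth-observation (EO) proxy variables and field
survey data: spectral index time series are collapsed into temporal
percentile metrics, a random-forest land-cover map supplies focal habitat
proportions, trapline and transect surveys are converted into relative
abundance indices, an all-relevant feature selection reduces the covariate
set, and a tuned random-forest regression predicts abundance over the
landscape, thresholded at the mean training prediction into a binary
optimal-habitat map. Because real Landsat/SRTM imagery and field tables for
such studies are rarely publishable, the package pairs every stage with a
synthetic-data generator that emulates the structure of those inputs with
known ground truth; all claims the test suite makes are claims about
recovery of that known truth.

## The synthetic landscape and scene generator

`generate_landscape()` builds a square 30 m grid (all coordinates are
projected metres; row 1 is the northern edge and coordinates follow the
pixel-centre convention). The DEM is a Gaussian random field smoothed with
a separable kernel (`dem_smooth = 10` pixels by default) and rescaled to a
mountain-valley range of 1300-3450 m. Land cover (eight classes: grassland,
woodland, arable, bushes, built-up, bare, water, snow) is derived from a
second smoothed field correlated with elevation (`dem_weight = 0.35`), with
two elevation rules applied first: snow occupies the highest pixels and
water the valley bottoms. The remaining classes are assigned by quantile
thresholds along the cover-score gradient, so realized class fractions
match the requested composition up to integer rounding. The default
composition (50% grassland, 15% woodland, 10% arable, 10% bare, 6% bushes,
4% built-up, 3% snow, 2% water) reflects a grassland-dominated valley
system with interspersed woodland.

Each land-cover class follows a Gaussian-bump NDVI phenology,
`NDVI(t) = base + amp * exp(-((t - peak) / width)^2)` with `t` in day of
year. This is the minimal seasonal model that gives the percentile metrics
something real to measure: grassland peaks at NDVI 0.70 around day 200,
arable has a short, tall bump (harvest), bare and built-up stay flat and
low, water is negative. Reflectances are recovered by inverting the NDVI
identity (`nir = red (1 + NDVI) / (1 - NDVI)`) with the class's fixed red
reflectance, blue = 0.5 red, green = 0.8 red, SWIR1 = `swir_factor` x NIR
and SWIR2 = 0.85 SWIR1. Multiplicative log-normal noise (class
`noise_sd`, default 0.03) perturbs every band independently, and bands are
clamped to a physically plausible range. Cloud/shadow masks are spatially
coherent blobs grown from random seed pixels by stochastic dilation until
the target coverage (default 25% per scene) is reached; coherent gaps
stress the per-pixel percentile logic far more than salt-and-pepper
masking would. The generator does not attempt radiative-transfer realism,
topographic illumination, sensor noise models, or inter-annual population
cycles — so a passing test suite demonstrates that the algorithms recover
a *structurally faithful* synthetic truth, not that they would achieve the
same numbers on real imagery.

## Spectral indices and temporal percentile metrics

`compute_index()` implements the standard formulations of NDVI, NDWI,
MNDWI, EVI, GRVI, DVI, TVI, SVVI and SAVI; `tasseled_cap()` applies the
published TM (Crist 1985, reflectance factors) and OLI (Baig et al. 2014)
coefficient sets selected by the scene's sensor tag. Two conventions
deserve note. NDWI is the Gao NIR-SWIR vegetation-moisture form, because
the green-SWIR open-water index is carried separately as MNDWI; the
McFeeters green-NIR form is available as `NDWI_MCF`. TVI is the Broge &
Leblanc triangular form and SVVI the Coulter all-band minus infrared-band
standard deviation, the most common definitions under those names. Pixels
where a normalized-difference denominator is zero are masked rather than
clamped — masked pixels are already first-class citizens because of cloud
masking.

`percentile_metrics()` collapses each pixel's valid observations into the
5th, 10th, 25th, 50th, 75th, 90th and 95th percentiles, the full range,
and the 75-25, 90-10 and 95-5 inter-percentile ranges. Percentiles use
linear interpolation between the closest order statistics (`quantile()`
type 7, the scientific-computing default) — the estimator is not dictated
by the problem, so the common default was chosen and is pinned by a
brute-force sort-and-interpolate oracle in the tests. Pixels with fewer
than `min_obs = 3` valid observations are masked rather than filled:
percentiles of one or two points are degenerate, and gap-filling is out of
scope. The median band composite for classification is definitionally the
p50 path applied to raw bands, and the tests assert that equivalence.

## Land cover, terrain and focal proportions

The classification stack is the six median bands, NDVI p10/p90/r90_10, and
elevation, slope and aspect (12 layers). Slope and aspect use Horn's
eight-neighbour finite differences with edge-replicated borders; aspect is
a compass bearing of steepest descent with `-1` as the flat-cell sentinel.
Training data are rectangular class-pure polygons extracted from the truth
map (emulating digitised homogeneous areas); up to 5000 pixels per class
(2000 in the demo configuration, which has only 25,600 pixels) are sampled
with replacement if scarce, and a 200-tree random forest classifies all
valid pixels. Accuracy is assessed on held-out reference points never used
in training.

Focal habitat proportions are computed for grassland, woodland and arable
in circular neighbourhoods of radius 50-500 m in 50 m steps (a pixel
belongs to the neighbourhood when its centre lies within the radius of the
focal pixel's centre; the 50 m kernel on 30 m pixels therefore spans the
full 3x3 block, diagonal centres being 42.4 m away). Radius, rather than
diameter, is the interpretation used; it is configurable. Border pixels
use the truncated in-grid neighbourhood rather than padding, which avoids
inventing land cover outside the study area. The implementation sums
row-runs of cumulative sums (exact integer counts, no FFT rounding) and is
pinned to an O(n^2 k) double-loop oracle in the tests.

## Survey abundance indices

Trapline surveys follow the standard design: 25 break-back traps of a
single kind per line, three control nights. Nightly captures are Poisson
with intensity `accessible x A(x) x exp(beta_type I[bbbt] +
beta_night (night - 1) + u_line)`, truncated at the number of accessible
traps. Traps are reset every morning, so the effort offset for a night is
the number of operational traps that night — equivalently free traps plus
traps that captured the target species. With no other process this offset
would be constant; the generator therefore models a small per-night trap
loss probability (`trap_loss = 0.03`, for theft/damage), which is what
makes the offset informative. Sprung-empty traps are not modelled.

`fit_capture_model()` fits the Poisson mixed model
`captures ~ trap_type + night + (1 | line) + offset(log(accessible))` by
Laplace-approximated maximum likelihood (lme4, bobyqa optimiser), and
gates the index definition on Wald tests at alpha = 0.05. When a nuisance
effect is significant, the index for a line is the mean *response-scale
residual against the population-level fit* (fixed effects plus offset,
random effect excluded). This choice matters: residuals against the full
conditional fit would have the line-level abundance signal absorbed into
the random intercept and carry no information at all. Response-scale
residuals keep the index in capture units; Pearson residuals are available
by option. When no nuisance effect is significant the index falls back to
raw captures per 100 trap-nights of nominal effort (25 traps x nights).
The path taken is recorded on the output.

Transect records score 20 intervals of 10 paces (0.8 m per pace, so 8 m
interval spacing) for species activity signs; the transect score is the
count of positive intervals (0-20) and the unit location is the mean of
interval coordinates. Presence per interval is Bernoulli with a logistic
link on the latent abundance. Because a Binomial(20) score carries
irreducible noise of up to variance 5, transect-based models plateau
around LOOCV R-squared 0.55-0.70 in the synthetic scenario — visibly lower
than trapline models, and a useful reminder that the two survey modes are
not interchangeable.

Spatial autocorrelation of the indices is reported (not gated) via global
Moran's I with binary distance-band weights (default 1.5 km,
row-unstandardized) with a permutation p-value (999 permutations,
two-sided on |I - E[I]| with E[I] = -1/(n-1)), plus an empirical
semivariogram with flagged empty bins. No pass/fail verdict is attached:
the assessment of "no autocorrelation" in this kind of study is a
judgement call, and the synthetic abundance surfaces are spatially
structured by construction.

## All-relevant feature selection

`boruta_select()` is a from-scratch implementation of shadow-feature
all-relevant selection for a continuous response. Each iteration appends
independently permuted "shadow" copies of the covariates, fits a
regression forest (500 trees, mtry = p/3), and scores a hit for every
still-undecided covariate whose importance exceeds the maximum shadow
importance. Cumulative hit counts are tested against Binomial(iterations,
0.5) with Bonferroni correction over the covariates at alpha = 0.01;
significantly many hits confirm, significantly few reject, and rejected
covariates leave the real side of the forest. Covariates undecided after
100 iterations are resolved by the rough fix (median importance against
the median of the per-iteration shadow maxima), recorded separately as
`tentative_confirmed` / `tentative_rejected`; both confirmed classes are
passed downstream, since a hard in/out split is what the SDM needs.

Two design choices depart from the textbook recipe, both motivated by
measured failure modes at small n. First, importance is the forest's raw
(unscaled) out-of-bag permutation importance — mean increase in OOB MSE —
rather than the z-scaled version: dividing by the per-tree standard error
inflates weak-but-consistent chance associations relative to the shadow
maximum. Second, the shadow pool never shrinks below 20 columns: as
covariates are rejected their permuted copies keep serving as shadows.
With the canonical ever-shrinking pool, the last survivors compete against
a handful of weak shadows, and at n = 60 a covariate whose only merit is a
chance correlation of |r| ~ 0.3 with the response can then accumulate a
significant hit record. The floor keeps the maximum-shadow reference
competitive throughout. Even so, all-relevant selection at n = 60 against
p = 40 has fundamental limits: a permuted response still contains realized
sample correlations up to |r| ~ 0.4, which are conditionally real and will
occasionally be confirmed by any method of this family, and an informative
covariate whose realized correlation happens to be weak in one draw can be
missed. The acceptance suite measures both failure directions explicitly.
A related effect appears in the full pipeline: with ten collinear focal
proportion layers of the driving habitat class in the covariate set, a
correlated index metric can be rejected because its conditional
contribution is diluted — the signal is retained, but by the proportion
layers.

`permutation_importance()` is the explicit form of the same statistic
(permute a column, re-predict out-of-bag, average the MSE increase over
repeats) and is used for the reported importance rankings and as an
independent cross-check of the native accounting.

## The species distribution model

Covariates are extracted at the pixel containing each unit's
representative coordinate (no interpolation — fractional and categorical
covariates make bilinear averaging meaningless); units on masked pixels
are dropped with a logged count. The regression forest exposes the
hyperparameters that matter for this model family: number of trees,
minimum leaf population, maximum terminal nodes (`NA` = unlimited; a cap
above the achievable leaf count is treated as no cap), variables per split
(`NA` = sqrt(p) rule) and bag fraction, implemented as per-tree
subsampling *without* replacement at the stated fraction (0.7 default) —
a "bag fraction" below one implies subsampling, and the with-replacement
bootstrap remains available at fraction 1. Tuning evaluates a grid by
leave-one-out R-squared and returns the argmax, breaking ties toward
fewer trees and then smaller leaves; the default grid (trees 100/200,
leaf 1/5, nodes 50/unlimited, bag 0.7) spans the configurations this
model family actually distinguishes at n ~ 50.

LOOCV trains on n-1 units with a per-fold seed derived deterministically
from the master seed (results are independent of execution order) and
reports the coefficient of determination `1 - SSE/SST` as the primary
R-squared, with squared Pearson correlation alongside — "R-squared of
observed versus predicted" is ambiguous between the two, and they can
differ noticeably for forests, whose LOOCV predictions are biased toward
the training mean. The fitted forest predicts every unmasked pixel;
predictions are bounded by the training response range, as forest
averaging guarantees.

The optimal-habitat threshold is the arithmetic mean of the model's
predictions on all training units; a pixel is optimal iff its prediction
*strictly* exceeds the threshold (a constant surface at the threshold maps
to 0% optimal). Area statistics count optimal pixels times pixel area,
with masked pixels excluded from the denominator of the percentage.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit integer seed; `run_pipeline()`
fans a single master seed out per stage by hashing the stage name
(`stage_seed()`, a fixed integer recurrence, platform-independent, always
below 2^31). Rerunning an identical configuration reproduces bit-identical
outputs, verified by hashing every stage product. The ranger classifier
runs single-threaded for this reason.

The demo configuration — the scale at which the package documents and
tests itself — uses a 160 x 160 pixel (4.8 x 4.8 km) landscape, 12 scenes,
60 traplines, 40 transects, and two species with known covariate
dependence; the calibration simulations use 200 replicate surveys of 60
traplines (capture GLMM) and 500 replicates of 50 units (Moran's I). At
this scale the whole pipeline runs in well under a minute and recovers
LOOCV R-squared of about 0.80 (trapline) and 0.67 (transect), with
Spearman correlation of about 0.9 between the predicted and true
abundance surfaces for the trapline species. These sizes were chosen so
that the full chain remains comfortably interactive; the algorithms are
O(pixels) to O(pixels x kernel) and scale to full Landsat tiles in the
obvious way.

## Known limitations

Raster handling is deliberately minimal (matrices plus a grid spec, TIFF
with a JSON metadata sidecar) — there is no reprojection, resampling, or
multi-CRS support, and file outputs are not true GeoTIFFs. The synthetic
world has no temporal autocorrelation in its noise, no mixed pixels, no
registration error, and stationary phenology, all of which real imagery
has. The capture model assumes the offset definition holds exactly and
that trap interference between species is negligible. Boruta's limits at
small n are described above. None of the real-data figures of the kind of
study this package supports (land-cover accuracies, per-species R-squared,
optimal-habitat percentages) can be reproduced from synthetic data; the
synthetic results are analogues demonstrating recovery of a known truth,
not reproductions.
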