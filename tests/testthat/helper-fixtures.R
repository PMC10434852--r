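# Shared fixtures, built once per test run. Kept small: a 60 x 60 landscape
# with an 8-scene year is enough to exercise every stage.

fx_truth <- generate_landscape(60, 60, seed = 101)

fx_scenes <- generate_scene_collection(
  fx_truth, dates = seq(40, 320, length.out = 8), cloud_fraction = 0.2,
  seed = 102)

# cloud-free scene for pixelwise formula checks
fx_clear <- generate_scene_collection(
  fx_truth, dates = 200, cloud_fraction = 0, seed = 103)[[1]]

# a scene with iid uniform reflectance, for formula oracles
random_scene <- function(nr = 10, nc = 10, seed = 1, sensor = "TM") {
  set.seed(seed)
  bands <- lapply(stats::setNames(nm = c("blue", "green", "red", "nir",
                                         "swir1", "swir2")),
                  function(b) matrix(stats::runif(nr * nc, 0.01, 0.9), nr, nc))
  eo_scene(bands, valid = matrix(TRUE, nr, nc), doy = 180, sensor = sensor)
}

# constant-abundance surface on the fixture landscape
fx_flat_abundance <- function(a) {
  matrix(a, fx_truth$grid$nrow, fx_truth$grid$ncol)
}

# small feature set + species + trapline observations for SDM-side tests
fx_features <- local({
  ndvi <- lapply(fx_scenes, compute_index, "NDVI")
  pm <- percentile_metrics(ndvi, min_obs = 2)
  terr <- terrain_derivatives(fx_truth$dem)
  props <- proportion_layers(fx_truth$landcover,
                             kernels_m = c(100, 250))
  c(list(NDVI_p90 = pm$layers$p90, NDVI_r90_10 = pm$layers$r90_10,
         elevation = fx_truth$dem, slope = terr$slope),
    props)
})

fx_species <- species_effect_spec(
  "vole",
  terms = c(prop_grassland_250m = 1.8, NDVI_p90 = 1.2, elevation = -0.8),
  baseline = log(0.1))

fx_abundance <- generate_species_truth(fx_truth, fx_features, fx_species)
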