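#!/usr/bin/env Rscript
# Stage 1: simulate the study landscape and its Landsat-like scene
# collection. The landscape carries known ground truth (DEM, 8-class land
# cover, per-class phenology) so every later stage can be validated against
# what was actually generated.

source("analysis/00_common.R")

truth <- generate_landscape(
  nrow = CFG$grid$nrow, ncol = CFG$grid$ncol, px = CFG$grid$px,
  elev_range = CFG$landscape$elev_range,
  dem_smooth = CFG$landscape$dem_smooth,
  cover_smooth = CFG$landscape$cover_smooth,
  dem_weight = CFG$landscape$dem_weight,
  seed = stage_seed(MASTER_SEED, "landscape"))

scenes <- generate_scene_collection(
  truth, dates = CFG$scenes$dates, cloud_fraction = CFG$scenes$cloud_fraction,
  sensor = CFG$scenes$sensor, year = CFG$scenes$year,
  seed = stage_seed(MASTER_SEED, "scenes"))

print(truth)

fractions <- data.frame(
  class = names(truth$legend),
  requested = as.numeric(truth$class_fractions),
  realized = as.numeric(table(factor(truth$landcover,
                                     levels = truth$legend)) /
                          length(truth$landcover)))
write.csv(fractions, file.path(RESULTS_DIR, "landscape_class_fractions.csv"),
          row.names = FALSE)

masked <- vapply(scenes, function(s) mean(!s$valid), 0)
message(sprintf("%d scenes; cloud-masked fraction %.2f-%.2f (target %.2f)",
                length(scenes), min(masked), max(masked),
                CFG$scenes$cloud_fraction))
message(sprintf("snow line at %.0f m; elevation range %.0f-%.0f m",
                truth$snow_elev_min, min(truth$dem), max(truth$dem)))

write_raster(list(landcover = truth$landcover + 0),
             file.path(RESULTS_DIR, "truth_landcover.tif"),
             grid = truth$grid, integer = TRUE)
write_raster(list(dem = truth$dem), file.path(RESULTS_DIR, "dem.tif"),
             grid = truth$grid)

save_stage(truth, "truth")
save_stage(scenes, "scenes")
message("stage 1 done: landscape and ", length(scenes), " scenes cached")
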