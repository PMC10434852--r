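#!/usr/bin/env Rscript
# Stage 3: terrain derivatives, the 12-layer classification stack, the
# 200-tree random-forest land cover map, its accuracy against held-out
# reference points, and the nested focal land-cover proportions.

source("analysis/00_common.R")

truth <- load_stage("truth", "01_simulate_landscape.R")
metrics <- load_stage("metrics", "02_eo_metrics.R")
composite <- load_stage("composite", "02_eo_metrics.R")

terr <- terrain_derivatives(truth$dem, px = CFG$grid$px)
stack <- assemble_stack(composite, metrics$NDVI, truth$dem, terr)
message("stack layers: ", paste(stack$manifest, collapse = ", "))

polys <- make_training_polygons(truth, n_polys = CFG$landcover$n_polys,
                                patch = CFG$landcover$patch,
                                seed = stage_seed(MASTER_SEED, "polygons"))
lc <- classify_landcover(stack, polys,
                         n_per_class = CFG$landcover$n_per_class,
                         n_trees = CFG$landcover$n_trees,
                         seed = stage_seed(MASTER_SEED, "classify"))
ref <- sample_reference_points(truth, n_per_class = CFG$landcover$n_reference,
                               exclude = polys,
                               seed = stage_seed(MASTER_SEED, "reference"))
acc <- confusion_matrix(lc, ref)
message(sprintf("overall accuracy vs %d held-out reference points: %.2f%%",
                nrow(ref), acc$overall * 100))
write.csv(as.data.frame.matrix(acc$matrix),
          file.path(RESULTS_DIR, "confusion_matrix.csv"))
write.csv(data.frame(class = names(truth$legend)[match(rownames(acc$matrix),
                                                       truth$legend)],
                     producer = acc$producer, user = acc$user),
          file.path(RESULTS_DIR, "class_accuracies.csv"), row.names = FALSE)

props <- proportion_layers(lc, legend = truth$legend,
                           kernels_m = CFG$kernels_m, px = CFG$grid$px)
message(length(props), " focal proportion layers (",
        paste(range(CFG$kernels_m), collapse = "-"), " m kernels)")

write_raster(list(landcover = lc$map + 0),
             file.path(RESULTS_DIR, "classified_landcover.tif"),
             grid = truth$grid, integer = TRUE)

save_stage(terr, "terrain")
save_stage(lc, "landcover")
save_stage(props, "proportions")
message("stage 3 done")
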