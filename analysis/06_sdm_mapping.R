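#!/usr/bin/env Rscript
# Stage 6: hyperparameter tuning, leave-one-out validation, predictive
# abundance mapping, mean-threshold optimal habitat, and the final report
# tables (LOOCV R-squared per species; threshold, optimal area and % of
# total land per species).

source("analysis/00_common.R")

truth <- load_stage("truth", "01_simulate_landscape.R")
features <- load_stage("features", "04_survey_abundance.R")
observations <- load_stage("observations", "04_survey_abundance.R")
selections <- load_stage("selections", "05_feature_selection.R")

validation <- list()
areas <- list()
for (sp in names(selections)) {
  sel <- selections[[sp]]$boruta$selected
  tab <- selections[[sp]]$table
  tab_sel <- tab[, c("unit", "response", sel)]
  attr(tab_sel, "covariates") <- sel
  class(tab_sel) <- class(tab)

  tuned <- tune_hyperparameters(tab_sel,
                                seed = stage_seed(MASTER_SEED,
                                                  paste0("tune_", sp)))
  write.csv(tuned$table, file.path(RESULTS_DIR, paste0("tuning_", sp, ".csv")),
            row.names = FALSE)
  cv <- loocv(tab_sel, tuned$best,
              seed = stage_seed(MASTER_SEED, paste0("loocv_", sp)))
  fp <- fit_and_predict(tab_sel, tuned$best, features,
                        seed = stage_seed(MASTER_SEED, paste0("fit_", sp)))
  oh <- optimal_habitat(fp$prediction, fp$training_predictions)
  st <- area_stats(oh$optimal, px = CFG$grid$px)
  rho <- cor(as.vector(fp$prediction),
             as.vector(observations[[sp]]$truth_abundance),
             method = "spearman", use = "complete.obs")
  message(sprintf(
    "%s (%s): LOOCV R2 = %.3f (r2 = %.3f), threshold %.3f, optimal %.1f km2 (%.1f%%), rho(truth) %.2f",
    sp, observations[[sp]]$method, cv$r2, cv$r2_pearson, oh$threshold,
    st$optimal_km2, st$pct_total_land, rho))

  validation[[sp]] <- data.frame(
    species = sp, method = observations[[sp]]$method, n = cv$n,
    r2 = cv$r2, r2_pearson = cv$r2_pearson, spearman_truth = rho)
  areas[[sp]] <- data.frame(
    species = sp, method = observations[[sp]]$method,
    threshold = oh$threshold, optimal_km2 = st$optimal_km2,
    pct_total_land = st$pct_total_land)

  write_raster(list(prediction = fp$prediction),
               file.path(RESULTS_DIR, paste0("prediction_", sp, ".tif")),
               grid = truth$grid)
  write_raster(list(optimal = oh$optimal + 0),
               file.path(RESULTS_DIR, paste0("optimal_", sp, ".tif")),
               grid = truth$grid, integer = TRUE)
}

write.csv(do.call(rbind, validation),
          file.path(RESULTS_DIR, "loocv_validation.csv"), row.names = FALSE)
write.csv(do.call(rbind, areas),
          file.path(RESULTS_DIR, "optimal_habitat_areas.csv"),
          row.names = FALSE)
message("stage 6 done: see results/loocv_validation.csv and ",
        "results/optimal_habitat_areas.csv")
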