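#!/usr/bin/env Rscript
# Stage 5: extract covariates at survey locations and run the all-relevant
# (Boruta-style) shadow-feature selection per species, with a permutation
# importance ranking of the retained covariates.

source("analysis/00_common.R")

truth <- load_stage("truth", "01_simulate_landscape.R")
features <- load_stage("features", "04_survey_abundance.R")
observations <- load_stage("observations", "04_survey_abundance.R")

selections <- list()
for (sp in names(observations)) {
  tab <- build_feature_table(features, observations[[sp]]$obs, truth$grid)
  message(sprintf("%s: %d units x %d covariates (%d dropped on masked pixels)",
                  sp, nrow(tab), length(attr(tab, "covariates")),
                  attr(tab, "n_dropped")))
  bor <- boruta_select(tab, alpha = CFG$boruta$alpha,
                       max_iter = CFG$boruta$max_iter,
                       n_trees = CFG$boruta$n_trees,
                       seed = stage_seed(MASTER_SEED, paste0("boruta_", sp)))
  print(bor)
  rank <- importance_ranking(tab, bor$selected,
                             seed = stage_seed(MASTER_SEED,
                                               paste0("rank_", sp)))
  message("top 5 by permutation importance: ",
          paste(utils::head(rank$covariate, 5), collapse = ", "))
  write.csv(rank, file.path(RESULTS_DIR, paste0("importance_", sp, ".csv")),
            row.names = FALSE)
  selections[[sp]] <- list(table = tab, boruta = bor, ranking = rank)
}

jsonlite::write_json(
  lapply(selections, function(s) {
    list(selected = s$boruta$selected,
         decision = as.list(stats::setNames(as.character(s$boruta$decision),
                                            names(s$boruta$decision))),
         hits = as.list(s$boruta$hits),
         iterations = s$boruta$iterations,
         alpha = s$boruta$alpha)
  }),
  file.path(RESULTS_DIR, "boruta_selection.json"),
  auto_unbox = TRUE, digits = NA)

save_stage(selections, "selections")
message("stage 5 done")
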