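# Shared setup for the numbered analysis scripts: one configuration, one
# master seed, and a small cache so each stage can hand its products to the
# next without recomputation. Run the scripts in order from the repository
# root:
#
#   Rscript analysis/01_simulate_landscape.R
#   Rscript analysis/02_eo_metrics.R
#   ...
#
# All numerical work lives in the optihab package; these scripts only
# orchestrate and report.

library(optihab)

MASTER_SEED <- 1
CFG <- demo_config(seed = MASTER_SEED)

RESULTS_DIR <- "results"
CACHE_DIR <- file.path(RESULTS_DIR, "cache")
dir.create(CACHE_DIR, recursive = TRUE, showWarnings = FALSE)

cache_path <- function(name) file.path(CACHE_DIR, paste0(name, ".rds"))

save_stage <- function(object, name) {
  saveRDS(object, cache_path(name))
  invisible(object)
}

load_stage <- function(name, producer) {
  p <- cache_path(name)
  if (!file.exists(p)) {
    stop(sprintf("missing '%s' - run analysis/%s first", name, producer),
         call. = FALSE)
  }
  readRDS(p)
}
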