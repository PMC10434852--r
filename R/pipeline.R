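#' Demonstration pipeline configuration
#'
#' The default end-to-end scenario: a 160 x 160 pixel (4.8 x 4.8 km) 30 m
#' landscape with the default class composition, twelve scene acquisitions
#' spread over the year with 25% cloud cover each, two species with known
#' covariate dependence (a grassland specialist surveyed by traplines and a
#' woodland specialist surveyed by transects), and the full
#' metrics/classification/selection/SDM chain. The transect species is a
#' subterranean grassland/arable dweller (activity signs scored on walked
#' transects), the trapline species a grassland vole.
#'
#' @param seed Master seed fanned out to every stochastic stage via
#'   [stage_seed()].
#' @return Nested configuration list (YAML-serialisable via
#'   [write_config()]).
#' @export
demo_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    grid = list(nrow = 160, ncol = 160, px = 30),
    landscape = list(elev_range = c(1300, 3450), dem_smooth = 10,
                     cover_smooth = 5, dem_weight = 0.35),
    scenes = list(dates = seq(30, 330, length.out = 12), cloud_fraction = 0.25,
                  sensor = "OLI", year = 2014),
    indices = c("NDVI", "NDWI", "MNDWI", "EVI", "GRVI", "DVI", "TVI",
                "SVVI", "SAVI", "TCB", "TCG", "TCW"),
    metric_indices = c("NDVI", "NDWI", "TCB", "TCW"), # SDM covariate subset
    min_obs = 3,
    landcover = list(n_per_class = 2000, n_trees = 200, n_polys = 12,
                     patch = 3, n_reference = 60),
    kernels_m = seq(50, 500, by = 50),
    survey = list(n_traplines = 60, n_transects = 40, nights = 3,
                  traps_per_line = 25, intervals = 20,
                  autocorr_radius = 1500, n_permutations = 199),
    boruta = list(alpha = 0.01, max_iter = 100, n_trees = 500),
    species = list(
      list(name = "grassland_vole", method = "trapline",
           terms = list(prop_grassland_250m = 1.8, NDVI_p90 = 1.2,
                        elevation = -0.8),
           baseline = log(0.1), beta_type = 0.7, beta_night = -0.15,
           trapline_sd = 0.3),
      list(name = "mole_vole", method = "transect",
           terms = list(NDVI_p50 = 1.0, prop_arable_250m = 0.8, slope = -0.5),
           baseline = log(0.6), transect_a = -3.5, transect_b = 4)
    )
  )
}

species_spec_from_config <- function(sp) {
  species_effect_spec(
    species = sp$name, terms = unlist(sp$terms),
    baseline = sp$baseline %||% log(0.05),
    beta_type = sp$beta_type %||% 0.7,
    beta_night = sp$beta_night %||% -0.15,
    trapline_sd = sp$trapline_sd %||% 0.3,
    transect_a = sp$transect_a %||% -2,
    transect_b = sp$transect_b %||% 2
  )
}

#' Run the full pipeline on a configuration
#'
#' Executes simulate -> indices -> composites -> classify -> proportions ->
#' survey -> select -> tune -> fit -> predict -> threshold -> report in
#' order, logging each stage, and returns one SDM result per species plus a
#' run manifest of output hashes (rerunning an identical configuration
#' reproduces identical hashes).
#'
#' @param config Configuration list, see [demo_config()].
#' @param out_dir Optional directory for file outputs (rasters, tables); no
#'   files are written when `NULL`.
#' @param verbose Log stage progress to stderr.
#' @return Object of class `pipeline_result`: list with `sdm` (per-species
#'   results), `landcover_accuracy`, `autocorrelation`, `features`,
#'   `truth`, `manifest` (named hash vector), `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  manifest <- c()
  note <- function(name, obj) {
    manifest[[name]] <<- rlang::hash(obj)
    obj
  }

  say("[simulate] landscape %d x %d", config$grid$nrow, config$grid$ncol)
  truth <- generate_landscape(
    nrow = config$grid$nrow, ncol = config$grid$ncol, px = config$grid$px,
    elev_range = config$landscape$elev_range,
    dem_smooth = config$landscape$dem_smooth,
    cover_smooth = config$landscape$cover_smooth,
    dem_weight = config$landscape$dem_weight,
    seed = stage_seed(seed, "landscape"))
  note("landscape", truth[c("dem", "landcover")])

  say("[simulate] %d scenes, cloud fraction %.2f",
      length(config$scenes$dates), config$scenes$cloud_fraction)
  scenes <- generate_scene_collection(
    truth, dates = config$scenes$dates,
    cloud_fraction = config$scenes$cloud_fraction,
    sensor = config$scenes$sensor, year = config$scenes$year,
    seed = stage_seed(seed, "scenes"))
  note("scenes", lapply(scenes, function(s) s$bands$red))

  say("[indices] computing %d index layers per scene", length(config$indices))
  index_series <- lapply(config$indices, function(nm) {
    lapply(scenes, function(s) compute_all_indices(s, nm)[[nm]])
  })
  names(index_series) <- config$indices

  say("[composites] percentile metrics + median composite")
  metrics <- lapply(index_series, percentile_metrics, min_obs = config$min_obs)
  composite <- median_composite(scenes)
  note("metrics", lapply(metrics, function(m) m$layers$p50))

  say("[classify] terrain, stack, %d-tree land cover",
      config$landcover$n_trees)
  terr <- terrain_derivatives(truth$dem, px = config$grid$px)
  stack <- assemble_stack(composite, metrics$NDVI, truth$dem, terr)
  polys <- make_training_polygons(truth, n_polys = config$landcover$n_polys,
                                  patch = config$landcover$patch,
                                  seed = stage_seed(seed, "polygons"))
  lc <- classify_landcover(stack, polys,
                           n_per_class = config$landcover$n_per_class,
                           n_trees = config$landcover$n_trees,
                           seed = stage_seed(seed, "classify"))
  ref <- sample_reference_points(truth,
                                 n_per_class = config$landcover$n_reference,
                                 exclude = polys,
                                 seed = stage_seed(seed, "reference"))
  acc <- confusion_matrix(lc, ref)
  say("[classify] overall accuracy %.3f", acc$overall)
  note("landcover_map", lc$map)

  say("[proportions] focal layers, kernels %s m",
      paste(range(config$kernels_m), collapse = "-"))
  props <- proportion_layers(lc, legend = truth$legend,
                             kernels_m = config$kernels_m,
                             px = config$grid$px)
  note("proportions", props)

  # SDM covariate set: percentile metrics of the configured indices,
  # focal proportions and terrain
  features <- list()
  for (nm in config$metric_indices) {
    for (ln in c("p10", "p25", "p50", "p75", "p90", "range", "r90_10")) {
      features[[paste0(nm, "_", ln)]] <- metrics[[nm]]$layers[[ln]]
    }
  }
  features <- c(features, props,
                list(elevation = truth$dem, slope = terr$slope,
                     aspect = terr$aspect))
  note("features", names(features))

  results <- list()
  autoc <- list()
  for (sp_cfg in config$species) {
    sp <- species_spec_from_config(sp_cfg)
    say("[survey] %s (%s)", sp$species, sp_cfg$method)
    missing_cov <- setdiff(names(sp$terms), names(features))
    if (length(missing_cov)) {
      stop(sprintf("stage species/%s: unknown covariate(s): %s",
                   sp$species, paste(missing_cov, collapse = ", ")))
    }
    A <- generate_species_truth(truth, features, sp)
    if (sp_cfg$method == "trapline") {
      records <- generate_trapline_survey(
        truth, A, n_traplines = config$survey$n_traplines, spec = sp,
        nights = config$survey$nights,
        traps_per_line = config$survey$traps_per_line,
        seed = stage_seed(seed, paste0("trapline_", sp$species)))
      model <- fit_capture_model(records)
      obs <- abundance_indices(model, species = sp$species)
    } else {
      records <- generate_transect_survey(
        truth, A, n_transects = config$survey$n_transects, spec = sp,
        intervals = config$survey$intervals,
        seed = stage_seed(seed, paste0("transect_", sp$species)))
      obs <- transect_scores(records, intervals = config$survey$intervals,
                             species = sp$species)
    }
    autoc[[sp$species]] <- morans_i(
      obs$value, obs[, c("x", "y")],
      radius = config$survey$autocorr_radius,
      n_permutations = config$survey$n_permutations,
      seed = stage_seed(seed, paste0("moran_", sp$species)))

    say("[select] Boruta for %s", sp$species)
    tab <- build_feature_table(features, obs, truth$grid)
    bor <- boruta_select(tab, alpha = config$boruta$alpha,
                         max_iter = config$boruta$max_iter,
                         n_trees = config$boruta$n_trees,
                         seed = stage_seed(seed, paste0("boruta_", sp$species)))
    sel <- bor$selected
    if (length(sel) == 0) sel <- names(features) # degenerate: keep all
    tab_sel <- tab[, c("unit", "response", sel)]
    attr(tab_sel, "covariates") <- sel
    class(tab_sel) <- class(tab)

    say("[tune/fit] %d selected covariates", length(sel))
    tuned <- tune_hyperparameters(tab_sel,
                                  seed = stage_seed(seed, paste0("tune_", sp$species)))
    cv <- loocv(tab_sel, tuned$best,
                seed = stage_seed(seed, paste0("loocv_", sp$species)))
    fitpred <- fit_and_predict(tab_sel, tuned$best, features,
                               seed = stage_seed(seed, paste0("fit_", sp$species)))
    opt <- optimal_habitat(fitpred$prediction, fitpred$training_predictions)
    area <- area_stats(opt$optimal, px = config$grid$px)
    rho <- stats::cor(as.vector(fitpred$prediction), as.vector(A),
                      method = "spearman", use = "complete.obs")
    say("[report] %s: LOOCV R2 = %.3f, threshold = %.3f, optimal = %.1f%%",
        sp$species, cv$r2, opt$threshold, area$pct_total_land)
    res <- list(species = sp$species, method = sp_cfg$method,
                selected = sel, boruta = bor, params = tuned$best,
                tuning_table = tuned$table, loocv = cv,
                prediction = fitpred$prediction,
                training_predictions = fitpred$training_predictions,
                threshold = opt$threshold, optimal = opt$optimal,
                area = area, spearman_truth = rho,
                observations = obs, truth_abundance = A)
    note(paste0("sdm_", sp$species),
         list(res$prediction, res$threshold, res$loocv$predicted))
    results[[sp$species]] <- res
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_raster(list(landcover = lc$map + 0), file.path(out_dir, "landcover.tif"),
                 grid = truth$grid, integer = TRUE)
    write_raster(list(dem = truth$dem), file.path(out_dir, "dem.tif"),
                 grid = truth$grid)
    for (sp in names(results)) {
      write_raster(list(prediction = results[[sp]]$prediction),
                   file.path(out_dir, paste0("prediction_", sp, ".tif")),
                   grid = truth$grid)
      write_raster(list(optimal = results[[sp]]$optimal + 0),
                   file.path(out_dir, paste0("optimal_", sp, ".tif")),
                   grid = truth$grid, integer = TRUE)
    }
    report <- do.call(rbind, lapply(results, function(r) {
      data.frame(species = r$species, method = r$method,
                 r2 = r$loocv$r2, threshold = r$threshold,
                 optimal_km2 = r$area$optimal_km2,
                 pct_total_land = r$area$pct_total_land)
    }))
    utils::write.csv(report, file.path(out_dir, "sdm_report.csv"),
                     row.names = FALSE)
  }

  structure(list(sdm = results, landcover_accuracy = acc,
                 autocorrelation = autoc, features = features,
                 landcover = lc, truth = truth,
                 manifest = unlist(manifest), config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d species, land-cover accuracy %.3f\n",
              length(x$sdm), x$landcover_accuracy$overall))
  for (r in x$sdm) {
    cat(sprintf("  %s (%s): LOOCV R2 %.3f, threshold %.3f, optimal %.1f%%\n",
                r$species, r$method, r$loocv$r2, r$threshold,
                r$area$pct_total_land))
  }
  invisible(x)
}
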