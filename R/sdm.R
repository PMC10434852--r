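#' Random-forest regression hyperparameters
#'
#' @param n_trees Number of trees (>= 1).
#' @param min_leaf Minimum leaf population (>= 1).
#' @param max_nodes Maximum terminal nodes, or `NA` for unlimited.
#' @param vps Variables per split; `NA` applies the `sqrt(p)` rule.
#' @param bag_fraction Per-tree subsample fraction in `(0, 1]`, drawn
#'   without replacement.
#' @return Object of class `rf_params`.
#' @export
rf_params <- function(n_trees = 200, min_leaf = 1, max_nodes = NA,
                      vps = NA, bag_fraction = 0.7) {
  stopifnot(n_trees >= 1, min_leaf >= 1, bag_fraction > 0, bag_fraction <= 1)
  structure(list(n_trees = n_trees, min_leaf = min_leaf,
                 max_nodes = max_nodes, vps = vps,
                 bag_fraction = bag_fraction),
            class = "rf_params")
}

# fit a regression forest under an rf_params spec; X data.frame, y numeric
fit_regression_forest <- function(X, y, params = rf_params(), seed = NULL,
                                  keep_inbag = FALSE, importance = FALSE) {
  p <- ncol(X)
  mtry <- if (is.na(params$vps)) max(1L, floor(sqrt(p))) else
    min(p, max(1L, params$vps))
  n <- length(y)
  sampsize <- max(2L, ceiling(params$bag_fraction * n))
  # a node cap above the achievable number of leaves is simply no cap
  maxnodes <- if (is.na(params$max_nodes)) NULL else
    min(params$max_nodes, sampsize)
  with_seed(seed, {
    randomForest::randomForest(
      x = X, y = y,
      ntree = params$n_trees,
      mtry = mtry,
      nodesize = params$min_leaf,
      maxnodes = maxnodes,
      replace = FALSE,
      sampsize = sampsize,
      keep.inbag = keep_inbag,
      importance = importance
    )
  })
}

#' Extract covariate values at survey unit locations
#'
#' Builds the unit-by-covariate feature table by looking up, for every
#' abundance observation, the value of each raster layer at the pixel
#' containing the unit's representative coordinate (no interpolation).
#' Units falling on a masked (`NA`) pixel of any layer are dropped, with
#' the dropped count recorded.
#'
#' @param rasters Named list of covariate matrices on `grid`.
#' @param observations Abundance observations (`unit`, `x`, `y`, `value`,
#'   ... as from [abundance_indices()] or [transect_scores()]).
#' @param grid A [grid_spec()].
#' @return Object of class `feature_table`: data.frame with `unit`,
#'   `response`, one column per raster layer; attributes `n_dropped` and
#'   `covariates`.
#' @export
build_feature_table <- function(rasters, observations, grid) {
  rc <- xy_to_rowcol(grid, observations$x, observations$y)
  if (anyNA(rc)) stop("observation coordinate outside the grid")
  cells <- rc[, "row"] + (rc[, "col"] - 1L) * grid$nrow
  X <- as.data.frame(lapply(rasters, function(r) r[cells]))
  names(X) <- names(rasters)
  keep <- stats::complete.cases(X)
  if (!any(keep)) stop("all units fall on masked pixels")
  out <- data.frame(unit = observations$unit[keep],
                    response = observations$value[keep],
                    X[keep, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "covariates") <- names(rasters)
  class(out) <- c("feature_table", "data.frame")
  out
}

# deterministic per-fold seed fan-out
fold_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  stage_seed(seed, paste0("fold", i))
}

#' Leave-one-out cross validation of a regression forest
#'
#' Each unit is predicted by a forest trained on the remaining `n - 1`
#' units, with a per-fold seed derived from the master seed so results are
#' reproducible and independent of execution order. Reports the coefficient
#' of determination `R2 = 1 - SSE/SST` (primary) and the squared Pearson
#' correlation of observed vs predicted (secondary).
#'
#' @param table A [build_feature_table()] result (or data.frame with
#'   `response` and covariate columns).
#' @param params An [rf_params()].
#' @param seed Master RNG seed.
#' @return List with `observed`, `predicted`, `r2`, `r2_pearson`, `n`.
#' @export
loocv <- function(table, params = rf_params(), seed = NULL) {
  y <- table$response
  n <- length(y)
  if (n < 3) stop("need at least 3 units for LOOCV")
  if (stats::sd(y) == 0) stop("constant response: R2 undefined")
  X <- table[, attr(table, "covariates") %||%
               setdiff(names(table), c("unit", "response")), drop = FALSE]
  X <- as.data.frame(X)
  pred <- vapply(seq_len(n), function(i) {
    fit <- fit_regression_forest(X[-i, , drop = FALSE], y[-i], params,
                                 seed = fold_seed(seed, i))
    as.numeric(stats::predict(fit, X[i, , drop = FALSE]))
  }, 0)
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  list(observed = y, predicted = pred,
       r2 = 1 - sse / sst,
       r2_pearson = suppressWarnings(stats::cor(y, pred))^2,
       n = n)
}

#' Hyperparameter tuning by LOOCV R-squared
#'
#' Evaluates every row of the tuning grid with [loocv()] and returns the
#' parameters with the highest coefficient of determination; ties break
#' toward fewer trees, then smaller minimum leaf population. The default
#' grid spans the tree count, leaf population, node cap and bag fraction
#' around the forest defaults (including the 200-tree, leaf-1, unlimited,
#' sqrt-p, 0.7-bag cell).
#'
#' @param table A [build_feature_table()] result.
#' @param grid data.frame of grid cells with columns `n_trees`, `min_leaf`,
#'   `max_nodes`, `vps`, `bag_fraction` (`NA` = unlimited / sqrt rule).
#' @param seed Master RNG seed.
#' @return List with `best` ([rf_params()]), `table` (the grid with an `r2`
#'   column, sorted decreasing).
#' @export
tune_hyperparameters <- function(table, grid = default_tuning_grid(),
                                 seed = NULL) {
  if (nrow(grid) == 0) stop("empty tuning grid")
  r2 <- vapply(seq_len(nrow(grid)), function(i) {
    p <- rf_params(grid$n_trees[i], grid$min_leaf[i], grid$max_nodes[i],
                   grid$vps[i], grid$bag_fraction[i])
    loocv(table, p, seed = seed)$r2
  }, 0)
  tab <- cbind(grid, r2 = r2)
  ord <- order(-tab$r2, tab$n_trees, tab$min_leaf)
  best <- tab[ord[1], ]
  list(best = rf_params(best$n_trees, best$min_leaf, best$max_nodes,
                        best$vps, best$bag_fraction),
       table = tab[ord, ])
}

#' Default hyperparameter tuning grid
#' @return data.frame of grid cells (tree count x leaf population x node
#'   cap, at the sqrt-p split rule and 0.7 bag fraction).
#' @export
default_tuning_grid <- function() {
  expand.grid(n_trees = c(100, 200), min_leaf = c(1, 5),
              max_nodes = c(50, NA), vps = NA, bag_fraction = 0.7)
}

#' Fit the final forest and predict an abundance surface
#'
#' Fits on all units and predicts at every pixel where all covariate
#' rasters are unmasked; masked pixels propagate as `NA`.
#'
#' @param table A [build_feature_table()] result.
#' @param params An [rf_params()].
#' @param rasters Named covariate matrices; names must cover the table's
#'   covariates.
#' @param seed RNG seed.
#' @return List with `model`, `prediction` (matrix), `training_predictions`
#'   (model predictions on the training units).
#' @export
fit_and_predict <- function(table, params, rasters, seed = NULL) {
  covs <- attr(table, "covariates") %||%
    setdiff(names(table), c("unit", "response"))
  missing_r <- setdiff(covs, names(rasters))
  if (length(missing_r)) {
    stop("missing covariate raster(s): ", paste(missing_r, collapse = ", "))
  }
  X <- as.data.frame(table[, covs, drop = FALSE])
  fit <- fit_regression_forest(X, table$response, params, seed = seed)
  dims <- dim(rasters[[covs[1]]])
  px_df <- as.data.frame(lapply(rasters[covs], as.vector))
  names(px_df) <- covs
  ok <- stats::complete.cases(px_df)
  pred <- rep(NA_real_, nrow(px_df))
  if (any(ok)) {
    pred[ok] <- stats::predict(fit, px_df[ok, , drop = FALSE])
  }
  list(model = fit,
       prediction = matrix(pred, dims[1], dims[2]),
       training_predictions = as.numeric(stats::predict(fit, X)))
}

#' Mean-threshold optimal habitat map
#'
#' The threshold is the arithmetic mean of the model's predictions on all
#' training units; a pixel is optimal iff its predicted abundance strictly
#' exceeds the threshold. Masked pixels stay masked.
#'
#' @param prediction Predicted-abundance matrix.
#' @param training_predictions Numeric vector of training-unit predictions.
#' @return List with `optimal` (0/1/NA integer matrix) and `threshold`.
#' @export
optimal_habitat <- function(prediction, training_predictions) {
  if (length(training_predictions) == 0) stop("no training predictions")
  thr <- mean(training_predictions)
  opt <- matrix(NA_integer_, nrow(prediction), ncol(prediction))
  ok <- !is.na(prediction)
  opt[ok] <- as.integer(prediction[ok] > thr)
  list(optimal = opt, threshold = thr)
}

#' Optimal-habitat area statistics
#'
#' @param optimal 0/1/NA optimal-habitat matrix.
#' @param px Pixel size (m).
#' @return List with `optimal_km2` and `pct_total_land` (% of unmasked
#'   pixels classified optimal).
#' @export
area_stats <- function(optimal, px = 30) {
  if (px <= 0) stop("pixel size must be positive")
  if (length(optimal) == 0) stop("empty map")
  n_opt <- sum(optimal == 1L, na.rm = TRUE)
  n_land <- sum(!is.na(optimal))
  if (n_land == 0) stop("empty map: all pixels masked")
  list(optimal_km2 = n_opt * px^2 / 1e6,
       pct_total_land = n_opt / n_land * 100)
}
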