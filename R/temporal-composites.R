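#' Apply a validity mask to a scene
#'
#' Pixels flagged invalid are excluded from every downstream statistic for
#' that scene (the scene's mask is intersected with the supplied one).
#'
#' @param scene An [eo_scene()].
#' @param mask Logical matrix on the same grid, `TRUE` = valid.
#' @return The masked `eo_scene`.
#' @export
mask_scene <- function(scene, mask) {
  if (!identical(dim(mask), dim(scene$valid))) {
    stop("mask grid does not match the scene grid")
  }
  scene$valid <- scene$valid & mask
  scene
}

#' Temporal percentile metrics of an index time series
#'
#' Collapses per-pixel index observations across a scene collection into the
#' percentile layers p5, p10, p25, p50, p75, p90, p95, the full range
#' (max - min) and the inter-percentile ranges r75_25, r90_10, r95_5.
#' Percentiles use linear interpolation between the closest order statistics
#' of the valid (unmasked) observations. Pixels with fewer than `min_obs`
#' valid observations are masked in every layer.
#'
#' @param index_list List of `index_raster`s for one index across scenes
#'   (as from [compute_index()] per scene), all on one grid.
#' @param min_obs Minimum valid observations per pixel (default 3).
#' @return Object of class `percentile_metrics`: list with `index` (name),
#'   `layers` (named list of matrices: `p5 ... p95, range, r75_25, r90_10,
#'   r95_5`), and `count` (integer matrix of valid observations).
#' @export
percentile_metrics <- function(index_list, min_obs = 3) {
  if (length(index_list) == 0) stop("empty scene collection")
  if (min_obs < 1) stop("min_obs must be >= 1")
  dims <- unique(lapply(index_list, function(i) dim(i$values)))
  if (length(dims) != 1) stop("index rasters are not on one grid")
  nr <- dims[[1]][1]; nc <- dims[[1]][2]
  obs <- vapply(index_list, function(i) as.vector(i$values),
                numeric(nr * nc))
  obs <- matrix(obs, nrow = nr * nc)
  count <- matrix(rowSums(!is.na(obs)), nr, nc)
  probs <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)
  q <- row_quantiles(obs, probs)
  lay <- function(v) {
    m <- matrix(v, nr, nc)
    m[count < min_obs] <- NA_real_
    m
  }
  rng <- apply(obs, 1, function(r) {
    if (all(is.na(r))) NA_real_ else diff(range(r, na.rm = TRUE))
  })
  layers <- list(
    p5 = lay(q[, 1]), p10 = lay(q[, 2]), p25 = lay(q[, 3]),
    p50 = lay(q[, 4]), p75 = lay(q[, 5]), p90 = lay(q[, 6]),
    p95 = lay(q[, 7]),
    range = lay(rng),
    r75_25 = lay(q[, 5] - q[, 3]),
    r90_10 = lay(q[, 6] - q[, 2]),
    r95_5 = lay(q[, 7] - q[, 1])
  )
  structure(list(index = index_list[[1]]$name, layers = layers,
                 count = count, min_obs = min_obs),
            class = "percentile_metrics")
}

#' @export
print.percentile_metrics <- function(x, ...) {
  cat(sprintf("<percentile_metrics> %s: %d layers, %d x %d px, median count %g\n",
              x$index, length(x$layers), nrow(x$count), ncol(x$count),
              stats::median(x$count)))
  invisible(x)
}

#' Median band composite of a scene collection
#'
#' Per band and pixel, the median of the valid observations across scenes
#' (definitionally the p50 path of [percentile_metrics()] applied to raw
#' bands).
#'
#' @param scenes List of [eo_scene()]s on one grid.
#' @param min_obs Minimum valid observations per pixel (default 1).
#' @return Named list of six matrices (`blue ... swir2`), `NA` where fewer
#'   than `min_obs` observations exist.
#' @export
median_composite <- function(scenes, min_obs = 1) {
  if (length(scenes) == 0) stop("empty scene collection")
  out <- lapply(names(scenes[[1]]$bands), function(bn) {
    idx <- lapply(scenes, function(s) {
      v <- s$bands[[bn]]
      v[!s$valid] <- NA_real_
      structure(list(name = bn, values = v, valid = s$valid),
                class = "index_raster")
    })
    percentile_metrics(idx, min_obs = min_obs)$layers$p50
  })
  names(out) <- names(scenes[[1]]$bands)
  out
}
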