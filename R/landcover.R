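#' Assemble the land-cover classification stack
#'
#' The classification feature stack comprises the six median-composite
#' reflectance bands, the NDVI temporal metrics p10, p90 and r90_10, and the
#' three terrain layers (elevation, slope, aspect) — 12 named layers. Any
#' pixel masked in any layer is excluded from training and classification.
#'
#' @param composite Named list of six median band matrices
#'   ([median_composite()]).
#' @param ndvi_metrics A `percentile_metrics` for NDVI.
#' @param dem Elevation matrix.
#' @param terrain List with `slope` and `aspect` ([terrain_derivatives()]).
#' @return Object of class `feature_stack`: list with `layers` (named list
#'   of 12 matrices), `manifest` (layer names in order) and `valid`
#'   (logical matrix).
#' @export
assemble_stack <- function(composite, ndvi_metrics, dem, terrain) {
  layers <- c(
    stats::setNames(composite, paste0("median_", names(composite))),
    list(ndvi_p10 = ndvi_metrics$layers$p10,
         ndvi_p90 = ndvi_metrics$layers$p90,
         ndvi_r90_10 = ndvi_metrics$layers$r90_10,
         elevation = dem, slope = terrain$slope, aspect = terrain$aspect)
  )
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1) stop("stack layers are not on one grid")
  valid <- Reduce(`&`, lapply(layers, function(l) !is.na(l)))
  structure(list(layers = layers, manifest = names(layers), valid = valid),
            class = "feature_stack")
}

# pull a units x layers data.frame of stack values at linear pixel indices
stack_values_at <- function(stack, cells) {
  out <- as.data.frame(lapply(stack$layers, function(l) l[cells]))
  names(out) <- stack$manifest
  out
}

#' Random-forest land-cover classification
#'
#' Samples up to `n_per_class` training pixels per class by random
#' stratified sampling within that class's training polygons (with
#' replacement if fewer are available), fits an `n_trees`-tree random
#' forest on the stack layers and classifies every valid pixel.
#' Deterministic given `seed`.
#'
#' @param stack A `feature_stack` from [assemble_stack()].
#' @param polygons Training polygons ([make_training_polygons()]): data.frame
#'   with `class`, `code`, `rmin`, `rmax`, `cmin`, `cmax`.
#' @param n_per_class Training pixels sampled per class (default 5000).
#' @param n_trees Trees (default 200).
#' @param seed Integer RNG seed (required).
#' @return Object of class `landcover_map`: list with `map` (integer matrix,
#'   `NA` on invalid pixels), `legend`, `model` (ranger forest),
#'   `training_summary` (pixels per class) and `manifest`.
#' @export
classify_landcover <- function(stack, polygons, n_per_class = 5000,
                               n_trees = 200, seed) {
  if (missing(seed)) stop("seed is required")
  dims <- dim(stack$valid)
  legend_codes <- sort(unique(polygons$code))
  with_seed(seed, {
    train <- list()
    for (code in legend_codes) {
      polys <- polygons[polygons$code == code, , drop = FALSE]
      cells <- unlist(lapply(seq_len(nrow(polys)), function(i) {
        rr <- polys$rmin[i]:polys$rmax[i]
        cc <- polys$cmin[i]:polys$cmax[i]
        as.vector(outer(rr, (cc - 1) * dims[1], `+`))
      }))
      cells <- cells[stack$valid[cells]]
      if (length(cells) == 0) {
        stop(sprintf("class code %d has no valid training pixels", code))
      }
      pick <- cells[sample.int(length(cells), n_per_class,
                               replace = length(cells) < n_per_class)]
      train[[as.character(code)]] <- pick
    }
    n_train <- vapply(train, length, 0L)
    df <- stack_values_at(stack, unlist(train))
    df$class <- factor(rep(legend_codes, times = n_train))
    fit <- ranger::ranger(class ~ ., data = df, num.trees = n_trees,
                          seed = as.integer(seed), num.threads = 1)
    cells <- which(stack$valid)
    pred <- stats::predict(fit, stack_values_at(stack, cells),
                           num.threads = 1)$predictions
    map <- matrix(NA_integer_, dims[1], dims[2])
    map[cells] <- as.integer(as.character(pred))
    structure(list(map = map, legend = legend_codes, model = fit,
                   training_summary = n_train, manifest = stack$manifest),
              class = "landcover_map")
  })
}

#' Confusion matrix and accuracies against reference points
#'
#' @param lc_map A `landcover_map` (or a bare integer matrix).
#' @param reference data.frame with `row`, `col` and true class `code`.
#' @return List with `matrix` (reference classes in rows, mapped classes in
#'   columns), `overall` accuracy, and per-class `producer` and `user`
#'   accuracies.
#' @export
confusion_matrix <- function(lc_map, reference) {
  map <- if (inherits(lc_map, "landcover_map")) lc_map$map else lc_map
  if (any(reference$row < 1 | reference$row > nrow(map) |
            reference$col < 1 | reference$col > ncol(map))) {
    stop("reference point off-grid")
  }
  pred <- map[cbind(reference$row, reference$col)]
  codes <- sort(unique(c(reference$code, pred[!is.na(pred)])))
  cm <- table(factor(reference$code, levels = codes),
              factor(pred, levels = codes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("reference", "mapped")
  total <- sum(cm)
  list(matrix = cm,
       overall = sum(diag(cm)) / total,
       producer = diag(cm) / pmax(rowSums(cm), 1),
       user = diag(cm) / pmax(colSums(cm), 1))
}

# exact focal disc sums by row-wise cumulative sums: for each row offset dy
# the disc covers a contiguous column run, summed in O(1) per pixel.
focal_disc_sum <- function(m, radius_px) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  out <- matrix(0, nr, nc)
  R <- floor(radius_px)
  cols <- seq_len(nc)
  for (dy in -R:R) {
    w <- floor(sqrt(radius_px^2 - dy^2) + 1e-9)
    src <- (1:nr) + dy
    ok <- src >= 1 & src <= nr
    hi <- pmin(cols + w, nc) + 1L
    lo <- pmax(cols - w - 1L, 0L) + 1L
    out[ok, ] <- out[ok, ] + cs[src[ok], hi, drop = FALSE] -
      cs[src[ok], lo, drop = FALSE]
  }
  out
}

#' Focal land-cover proportion
#'
#' Per pixel, the fraction of pixels of the target class among all pixels
#' whose centres lie within `kernel_m` metres of the focal pixel centre
#' (circular neighbourhood; inclusive boundary). Border pixels use the
#' truncated in-grid neighbourhood.
#'
#' @param landcover Integer class matrix (a `landcover_map` is accepted).
#' @param class_code Target class code.
#' @param kernel_m Neighbourhood radius in metres (>= pixel size).
#' @param px Pixel size (m).
#' @return Matrix of proportions in `[0, 1]`.
#' @export
focal_proportion <- function(landcover, class_code, kernel_m, px = 30) {
  map <- if (inherits(landcover, "landcover_map")) landcover$map else landcover
  if (kernel_m < px) stop("kernel must be at least one pixel")
  r <- kernel_m / px
  target <- (map == class_code) * 1
  target[is.na(target)] <- 0
  counted <- matrix(1, nrow(map), ncol(map))
  focal_disc_sum(target, r) / focal_disc_sum(counted, r)
}

#' All nested focal proportion layers
#'
#' Proportional presence of the tracked habitat classes (grassland,
#' woodland, arable by default) in nested circular kernels (default radii
#' 50-500 m in 50 m steps). Classes absent from the map are skipped, so a
#' woodland-free area yields 20 layers instead of 30.
#'
#' @param landcover Integer class matrix or `landcover_map`.
#' @param legend Named class codes, default [landcover_legend()].
#' @param classes Tracked class names.
#' @param kernels_m Kernel radii (m).
#' @param px Pixel size (m).
#' @return Named list of proportion matrices, names like
#'   `prop_grassland_250m`.
#' @export
proportion_layers <- function(landcover, legend = landcover_legend(),
                              classes = c("grassland", "woodland", "arable"),
                              kernels_m = seq(50, 500, by = 50), px = 30) {
  map <- if (inherits(landcover, "landcover_map")) landcover$map else landcover
  out <- list()
  for (cl in classes) {
    code <- legend[[cl]]
    if (!any(map == code, na.rm = TRUE)) next
    for (k in kernels_m) {
      out[[sprintf("prop_%s_%dm", cl, k)]] <-
        focal_proportion(map, code, k, px = px)
    }
  }
  out
}
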