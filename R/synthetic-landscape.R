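#' Land-cover legend
#'
#' The eight-class legend used throughout: 1 grassland, 2 woodland, 3 arable,
#' 4 bushes, 5 built-up, 6 bare, 7 water, 8 snow.
#'
#' @return Named integer vector mapping class name to code.
#' @export
landcover_legend <- function() {
  c(grassland = 1L, woodland = 2L, arable = 3L, bushes = 4L,
    builtup = 5L, bare = 6L, water = 7L, snow = 8L)
}

#' Default landscape class fractions
#'
#' A mountain-valley composition: grassland dominated with interspersed
#' woodland, arable valley bottoms, minor bushes/built-up, high-altitude bare
#' and snow, and a little open water.
#'
#' @return Named numeric vector summing to 1 over the eight classes.
#' @export
default_class_fractions <- function() {
  c(grassland = 0.50, woodland = 0.15, arable = 0.10, bushes = 0.06,
    builtup = 0.04, bare = 0.10, water = 0.02, snow = 0.03)
}

#' Default per-class phenology and reflectance parameters
#'
#' Each land-cover class follows a Gaussian-bump NDVI trajectory over the
#' year, `NDVI(t) = base + amp * exp(-((t - peak)/width)^2)` with `t` in day
#' of year, inverted to band reflectances (see
#' [generate_scene_collection()]). `red` is the class's red reflectance,
#' `swir_factor` scales SWIR1 from NIR, and `noise_sd` is the s.d. of the
#' multiplicative log-normal band noise.
#'
#' @return data.frame with one row per class (rownames = class names) and
#'   columns `base_ndvi`, `amp_ndvi`, `peak_doy`, `width_doy`, `red`,
#'   `swir_factor`, `noise_sd`.
#' @export
default_phenology <- function() {
  p <- data.frame(
    base_ndvi   = c(0.25, 0.35, 0.15, 0.30, 0.12, 0.08, -0.35, 0.02),
    amp_ndvi    = c(0.45, 0.35, 0.55, 0.30, 0.05, 0.04,  0.03, 0.02),
    peak_doy    = c(200, 190, 180, 195, 180, 180, 180, 180),
    width_doy   = c(60, 70, 40, 65, 60, 60, 60, 60),
    red         = c(0.08, 0.05, 0.10, 0.07, 0.18, 0.24, 0.04, 0.50),
    swir_factor = c(0.55, 0.45, 0.70, 0.50, 1.00, 1.15, 0.15, 0.08),
    noise_sd    = rep(0.03, 8),
    row.names   = names(landcover_legend())
  )
  stopifnot(all(p$base_ndvi + p$amp_ndvi < 1))
  p
}

#' Generate a synthetic landscape with known ground truth
#'
#' Builds a DEM as a smoothed Gaussian random field rescaled to an elevation
#' range, and a land-cover map by quantile-thresholding a second correlated
#' field subject to elevation rules: snow occupies the highest-elevation
#' pixels and water the valley bottoms; the remaining classes are ordered
#' along the cover-score gradient (arable, built-up, grassland, bushes,
#' woodland, bare) so realized fractions match the requested ones up to
#' integer rounding. Deterministic given `seed`.
#'
#' @param nrow,ncol Grid dimensions in pixels.
#' @param px Pixel size (m), default 30.
#' @param class_fractions Named fractions over the 8 classes, summing to ~1.
#' @param elev_range Elevation range (m) the DEM is rescaled to.
#' @param dem_smooth,cover_smooth Field smoothing s.d. (pixels).
#' @param dem_weight Weight of the (standardized) DEM in the cover score;
#'   the remainder comes from an independent smoothed field.
#' @param phenology Per-class parameter table, default [default_phenology()].
#' @param seed Integer RNG seed (required).
#' @return An object of class `landscape_truth`: list with `grid`
#'   ([grid_spec()]), `dem` (matrix, m), `landcover` (integer matrix, codes
#'   1-8), `legend`, `class_params`, `snow_elev_min`.
#' @export
generate_landscape <- function(nrow, ncol, px = 30,
                               class_fractions = default_class_fractions(),
                               elev_range = c(1300, 3450),
                               dem_smooth = 10, cover_smooth = 5,
                               dem_weight = 0.35,
                               phenology = default_phenology(),
                               seed) {
  if (nrow <= 0 || ncol <= 0) stop("grid dimensions must be positive")
  if (missing(seed)) stop("seed is required")
  legend <- landcover_legend()
  cf <- class_fractions[names(legend)]
  cf[is.na(cf)] <- 0
  names(cf) <- names(legend)
  if (any(cf < 0 | cf > 1)) stop("class fractions must lie in [0, 1]")
  if (abs(sum(cf) - 1) > 0.01) stop("class fractions must sum to ~1")
  cf <- cf / sum(cf)

  with_seed(seed, {
    grid <- grid_spec(nrow, ncol, px = px)
    dem_field <- smooth_matrix(matrix(stats::rnorm(nrow * ncol), nrow, ncol),
                               dem_smooth)
    dem <- elev_range[1] + (dem_field - min(dem_field)) /
      max(max(dem_field) - min(dem_field), .Machine$double.eps) *
      diff(elev_range)

    cover_field <- smooth_matrix(matrix(stats::rnorm(nrow * ncol), nrow, ncol),
                                 cover_smooth)
    score <- (1 - dem_weight) * zscore(as.vector(cover_field)) +
      dem_weight * zscore(as.vector(dem))

    n <- nrow * ncol
    lc <- integer(n)
    # elevation rules first: snow on the highest pixels, water in the lowest
    # valley bottoms (by elevation, tie-broken by score for determinism)
    ord_elev <- order(as.vector(dem), score, decreasing = TRUE)
    n_snow <- round(cf["snow"] * n)
    if (n_snow > 0) lc[ord_elev[seq_len(n_snow)]] <- legend["snow"]
    remaining <- which(lc == 0L)
    n_water <- round(cf["water"] * n)
    if (n_water > 0) {
      ord_low <- remaining[order(dem[remaining], score[remaining])]
      lc[ord_low[seq_len(min(n_water, length(ord_low)))]] <- legend["water"]
    }
    # remaining classes along the cover-score gradient
    remaining <- which(lc == 0L)
    seq_classes <- c("arable", "builtup", "grassland", "bushes", "woodland", "bare")
    counts <- round(cf[seq_classes] / max(sum(cf[seq_classes]), .Machine$double.eps) *
                      length(remaining))
    # fix rounding so counts sum to the number of remaining pixels
    while (sum(counts) > length(remaining)) {
      counts[which.max(counts)] <- counts[which.max(counts)] - 1L
    }
    while (sum(counts) < length(remaining)) {
      counts[which.max(counts)] <- counts[which.max(counts)] + 1L
    }
    ord <- remaining[order(score[remaining])]
    at <- 1L
    for (cl in seq_classes) {
      k <- counts[[cl]]
      if (k > 0) {
        lc[ord[at:(at + k - 1L)]] <- legend[[cl]]
        at <- at + k
      }
    }
    landcover <- matrix(as.integer(lc), nrow, ncol)
    snow_elev_min <- if (n_snow > 0) min(dem[landcover == legend["snow"]]) else Inf

    structure(
      list(grid = grid, dem = dem, landcover = landcover, legend = legend,
           class_params = phenology, class_fractions = cf,
           snow_elev_min = snow_elev_min, seed = as.integer(seed)),
      class = "landscape_truth"
    )
  })
}

#' @export
print.landscape_truth <- function(x, ...) {
  cat(sprintf("<landscape_truth> %d x %d px @ %g m, elevation %.0f-%.0f m\n",
              x$grid$nrow, x$grid$ncol, x$grid$px, min(x$dem), max(x$dem)))
  fr <- table(factor(x$landcover, levels = x$legend,
                     labels = names(x$legend))) / length(x$landcover)
  print(round(fr, 3))
  invisible(x)
}

#' Extract rectangular training polygons from a landscape truth
#'
#' Emulates the digitisation of homogeneous training areas: finds, per
#' class, up to `n_polys` pure rectangular patches of the truth map (side
#' `patch` pixels, shrinking to single pixels where no pure patch exists).
#'
#' @param truth A `landscape_truth`.
#' @param n_polys Polygons per class.
#' @param patch Preferred patch side length (pixels).
#' @param seed RNG seed.
#' @return data.frame with columns `class` (name), `code`, `rmin`, `rmax`,
#'   `cmin`, `cmax` (pixel index bounds, inclusive).
#' @export
make_training_polygons <- function(truth, n_polys = 8, patch = 3, seed) {
  lc <- truth$landcover
  with_seed(seed, {
    out <- list()
    for (cl in names(truth$legend)) {
      code <- truth$legend[[cl]]
      if (!any(lc == code)) next # class absent from this landscape
      got <- 0L
      for (side in seq(patch, 1L)) {
        if (got >= n_polys) break
        cand <- which(lc == code, arr.ind = TRUE)
        cand <- cand[cand[, 1] <= nrow(lc) - side + 1 &
                       cand[, 2] <= ncol(lc) - side + 1, , drop = FALSE]
        if (nrow(cand) == 0) next
        cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
        for (i in seq_len(nrow(cand))) {
          if (got >= n_polys) break
          r <- cand[i, 1]; c <- cand[i, 2]
          block <- lc[r:(r + side - 1), c:(c + side - 1)]
          if (all(block == code)) {
            out[[length(out) + 1L]] <- data.frame(
              class = cl, code = code, rmin = r, rmax = r + side - 1L,
              cmin = c, cmax = c + side - 1L)
            got <- got + 1L
          }
        }
      }
      if (got == 0L) {
        stop(sprintf("no training pixels available for class '%s'", cl))
      }
    }
    do.call(rbind, out)
  })
}

#' Sample held-out reference points from a landscape truth
#'
#' @param truth A `landscape_truth`.
#' @param n_per_class Reference points per (present) class.
#' @param exclude Optional data.frame of training polygons
#'   ([make_training_polygons()]) whose pixels are excluded.
#' @param seed RNG seed.
#' @return data.frame with `row`, `col`, `x`, `y`, `code`, `class`.
#' @export
sample_reference_points <- function(truth, n_per_class = 100, exclude = NULL,
                                    seed) {
  lc <- truth$landcover
  excluded <- matrix(FALSE, nrow(lc), ncol(lc))
  if (!is.null(exclude)) {
    for (i in seq_len(nrow(exclude))) {
      excluded[exclude$rmin[i]:exclude$rmax[i],
               exclude$cmin[i]:exclude$cmax[i]] <- TRUE
    }
  }
  with_seed(seed, {
    out <- list()
    for (cl in names(truth$legend)) {
      code <- truth$legend[[cl]]
      cand <- which(lc == code & !excluded)
      if (length(cand) == 0) next
      pick <- cand[sample.int(length(cand), min(n_per_class, length(cand)))]
      rc <- arrayInd(pick, dim(lc))
      xy <- rowcol_to_xy(truth$grid, rc[, 1], rc[, 2])
      out[[length(out) + 1L]] <- data.frame(
        row = rc[, 1], col = rc[, 2], x = xy[, "x"], y = xy[, "y"],
        code = code, class = cl)
    }
    do.call(rbind, out)
  })
}
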