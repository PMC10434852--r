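# Synthetic scene generation: per-class Gaussian-bump NDVI phenology
# inverted to six-band surface reflectance, plus spatially coherent cloud
# masks grown by morphological dilation.

# fixed band-scaling constants (documented in the methods vignette)
BLUE_FROM_RED <- 0.5
GREEN_FROM_RED <- 0.8
SWIR2_FROM_SWIR1 <- 0.85

#' Construct a scene object
#'
#' @param bands Named list of six reflectance matrices
#'   (`blue, green, red, nir, swir1, swir2`).
#' @param valid Logical matrix; `TRUE` where the pixel is usable.
#' @param doy Acquisition day of year (1-366).
#' @param year Acquisition year.
#' @param sensor `"TM"` or `"OLI"` (selects tasselled-cap coefficients).
#' @param grid Optional [grid_spec()].
#' @return Object of class `eo_scene`.
#' @export
eo_scene <- function(bands, valid, doy, year = 2014L, sensor = "OLI",
                     grid = NULL) {
  need <- c("blue", "green", "red", "nir", "swir1", "swir2")
  if (!all(need %in% names(bands))) {
    stop("scene needs bands: ", paste(setdiff(need, names(bands)), collapse = ", "))
  }
  dims <- lapply(bands[need], dim)
  if (length(unique(dims)) != 1 || !identical(dim(valid), dims[[1]])) {
    stop("all bands and the validity mask must share one grid")
  }
  structure(list(bands = bands[need], valid = valid, doy = as.integer(doy),
                 year = as.integer(year), sensor = sensor, grid = grid),
            class = "eo_scene")
}

#' @export
print.eo_scene <- function(x, ...) {
  cat(sprintf("<eo_scene> %s doy %d (%d), %d x %d px, %.1f%% valid\n",
              x$sensor, x$doy, x$year, nrow(x$valid), ncol(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

# class NDVI trajectory at day-of-year t
phenology_ndvi <- function(params, t) {
  params$base_ndvi + params$amp_ndvi * exp(-((t - params$peak_doy) / params$width_doy)^2)
}

# grow spatially contiguous cloud blobs to roughly `fraction` coverage
grow_cloud_mask <- function(nr, nc, fraction) {
  cloud <- matrix(FALSE, nr, nc)
  if (fraction <= 0) return(cloud)
  npix <- nr * nc
  n_seeds <- max(1L, round(npix * fraction / 150))
  seeds <- sample.int(npix, n_seeds)
  cloud[seeds] <- TRUE
  while (mean(cloud) < fraction) {
    ring <- (rbind(cloud[-1, , drop = FALSE], FALSE) |
               rbind(FALSE, cloud[-nr, , drop = FALSE]) |
               cbind(cloud[, -1, drop = FALSE], FALSE) |
               cbind(FALSE, cloud[, -nc, drop = FALSE])) & !cloud
    idx <- which(ring)
    if (length(idx) == 0) break
    keep <- idx[stats::runif(length(idx)) < 0.7]
    if (length(keep) == 0) next
    # stop close to the target rather than overshooting by a whole ring
    deficit <- ceiling((fraction - mean(cloud)) * npix)
    if (length(keep) > deficit) keep <- sample(keep, deficit)
    cloud[keep] <- TRUE
  }
  cloud
}

#' Generate a collection of dated synthetic scenes
#'
#' For each acquisition date, every pixel's NDVI follows its land-cover
#' class's Gaussian-bump trajectory; band reflectances are recovered by
#' inverting the NDVI identity (`nir = red * (1 + NDVI) / (1 - NDVI)`) with
#' fixed blue/green/SWIR scalings, then perturbed by multiplicative
#' log-normal noise with the class's `noise_sd`. Spatially contiguous cloud
#' blobs covering approximately `cloud_fraction` of the grid are flagged
#' invalid in each scene's mask. Deterministic given `seed`.
#'
#' @param truth A `landscape_truth` from [generate_landscape()].
#' @param dates Integer vector of acquisition days of year (1-366).
#' @param cloud_fraction Expected masked fraction per scene, in `[0, 1)`.
#' @param sensor Sensor tag applied to every scene (`"TM"` or `"OLI"`).
#' @param year Acquisition year tag.
#' @param seed Integer RNG seed (required).
#' @return List of `eo_scene` objects, one per date.
#' @export
generate_scene_collection <- function(truth, dates, cloud_fraction = 0.25,
                                      sensor = "OLI", year = 2014L, seed) {
  if (any(dates < 1 | dates > 366)) stop("dates must be days of year in 1-366")
  if (cloud_fraction < 0 || cloud_fraction >= 1) {
    stop("cloud_fraction must lie in [0, 1)")
  }
  if (missing(seed)) stop("seed is required")
  params <- truth$class_params
  lc <- truth$landcover
  nr <- nrow(lc); nc <- ncol(lc)
  if (any(params$base_ndvi + params$amp_ndvi >= 1)) {
    stop("invalid phenology: NDVI trajectory reaches 1")
  }
  with_seed(seed, {
    lapply(dates, function(t) {
      ndvi_c <- phenology_ndvi(params, t)             # per class
      red_c <- params$red
      nir_c <- red_c * (1 + ndvi_c) / (1 - ndvi_c)
      cl <- as.vector(lc)
      mk <- function(v) matrix(v[cl], nr, nc)
      bands <- list(
        blue = mk(BLUE_FROM_RED * red_c),
        green = mk(GREEN_FROM_RED * red_c),
        red = mk(red_c),
        nir = mk(nir_c),
        swir1 = mk(params$swir_factor * nir_c),
        swir2 = mk(SWIR2_FROM_SWIR1 * params$swir_factor * nir_c)
      )
      noise_sd <- matrix(params$noise_sd[cl], nr, nc)
      bands <- lapply(bands, function(b) {
        b <- b * exp(matrix(stats::rnorm(nr * nc), nr, nc) * noise_sd)
        pmin(pmax(b, 1e-06), 1.5) # keep reflectance physically plausible
      })
      valid <- !grow_cloud_mask(nr, nc, cloud_fraction)
      eo_scene(bands, valid, doy = t, year = year, sensor = sensor,
               grid = truth$grid)
    })
  })
}
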