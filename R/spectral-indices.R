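#' Spectral index suite
#'
#' Computes one of the nine band-ratio vegetation/water indices from a
#' six-band surface-reflectance scene. Standard formulations are used:
#' \describe{
#'   \item{NDVI}{`(nir - red) / (nir + red)`}
#'   \item{NDWI}{Gao vegetation-moisture form `(nir - swir1) / (nir + swir1)`
#'     (the McFeeters open-water form `(green - nir) / (green + nir)` is
#'     available as `NDWI_MCF`)}
#'   \item{MNDWI}{`(green - swir1) / (green + swir1)`}
#'   \item{EVI}{`2.5 (nir - red) / (nir + 6 red - 7.5 blue + 1)`}
#'   \item{GRVI}{`(green - red) / (green + red)`}
#'   \item{DVI}{`nir - red`}
#'   \item{TVI}{triangular form `0.5 (120 (nir - green) - 200 (red - green))`}
#'   \item{SVVI}{`sd(all six bands) - sd(nir, swir1, swir2)` per pixel}
#'   \item{SAVI}{`1.5 (nir - red) / (nir + red + 0.5)`}
#' }
#' Pixels where a denominator is zero are masked, as are pixels invalid in
#' the scene's cloud/shadow/snow mask.
#'
#' @param scene An [eo_scene()].
#' @param name Index name (case-insensitive), one of
#'   `NDVI, NDWI, NDWI_MCF, MNDWI, EVI, GRVI, DVI, TVI, SVVI, SAVI`.
#' @return Object of class `index_raster`: list with `name`, `values`
#'   (matrix, `NA` where masked) and `valid` (logical matrix).
#' @export
compute_index <- function(scene, name) {
  b <- scene$bands
  nm <- toupper(name)
  nd <- function(a, c) (a - c) / (a + c)
  values <- switch(
    nm,
    NDVI = nd(b$nir, b$red),
    NDWI = nd(b$nir, b$swir1),
    NDWI_MCF = nd(b$green, b$nir),
    MNDWI = nd(b$green, b$swir1),
    EVI = 2.5 * (b$nir - b$red) / (b$nir + 6 * b$red - 7.5 * b$blue + 1),
    GRVI = nd(b$green, b$red),
    DVI = b$nir - b$red,
    TVI = 0.5 * (120 * (b$nir - b$green) - 200 * (b$red - b$green)),
    SVVI = pixel_sd(b) - pixel_sd(b[c("nir", "swir1", "swir2")]),
    SAVI = 1.5 * (b$nir - b$red) / (b$nir + b$red + 0.5),
    stop("unknown index name: ", name)
  )
  valid <- scene$valid & is.finite(values)
  values[!valid] <- NA_real_
  structure(list(name = nm, values = values, valid = valid),
            class = "index_raster")
}

# per-pixel standard deviation across a list of band matrices (sample sd)
pixel_sd <- function(bands) {
  k <- length(bands)
  m <- Reduce(`+`, bands) / k
  ss <- Reduce(`+`, lapply(bands, function(x) (x - m)^2))
  sqrt(ss / (k - 1))
}

# Published tasselled-cap coefficient sets (surface-reflectance bands in
# order blue, green, red, nir, swir1, swir2).
# TM: Crist (1985) reflectance-factor coefficients.
# OLI: Baig et al. (2014), Landsat 8 bands 2-7.
tasseled_cap_coefficients <- function(sensor) {
  tabs <- list(
    TM = rbind(
      brightness = c(0.2043, 0.4158, 0.5524, 0.5741, 0.3124, 0.2303),
      greenness  = c(-0.1603, -0.2819, -0.4934, 0.7940, -0.0002, -0.1446),
      wetness    = c(0.0315, 0.2021, 0.3102, 0.1594, -0.6806, -0.6109)
    ),
    OLI = rbind(
      brightness = c(0.3029, 0.2786, 0.4733, 0.5599, 0.5080, 0.1872),
      greenness  = c(-0.2941, -0.2430, -0.5424, 0.7276, 0.0713, -0.1608),
      wetness    = c(0.1511, 0.1973, 0.3283, 0.3407, -0.7117, -0.4559)
    )
  )
  out <- tabs[[toupper(sensor)]]
  if (is.null(out)) stop("unknown sensor tag: ", sensor)
  colnames(out) <- c("blue", "green", "red", "nir", "swir1", "swir2")
  out
}

#' Tasselled-cap transform
#'
#' Linear combination of the six reflectance bands into brightness,
#' greenness and wetness components, using the published sensor-specific
#' coefficient set selected by the scene's sensor tag (TM or OLI).
#'
#' @param scene An [eo_scene()] with a known sensor tag.
#' @return Named list of three `index_raster`s: `TCB`, `TCG`, `TCW`.
#' @export
tasseled_cap <- function(scene) {
  cf <- tasseled_cap_coefficients(scene$sensor)
  comp <- function(w) {
    v <- Reduce(`+`, Map(function(band, coeff) coeff * scene$bands[[band]],
                         colnames(cf), w))
    v[!scene$valid] <- NA_real_
    v
  }
  out <- list(
    TCB = structure(list(name = "TCB", values = comp(cf["brightness", ]),
                         valid = scene$valid), class = "index_raster"),
    TCG = structure(list(name = "TCG", values = comp(cf["greenness", ]),
                         valid = scene$valid), class = "index_raster"),
    TCW = structure(list(name = "TCW", values = comp(cf["wetness", ]),
                         valid = scene$valid), class = "index_raster")
  )
  out
}

#' Names of the supported index layers
#' @return Character vector of index identifiers (including the three
#'   tasselled-cap components).
#' @export
index_names <- function() {
  c("NDVI", "NDWI", "MNDWI", "EVI", "GRVI", "DVI", "TVI", "SVVI", "SAVI",
    "TCB", "TCG", "TCW")
}

#' Compute all index layers of a scene
#'
#' Convenience wrapper: the nine band-ratio indices plus the three
#' tasselled-cap components.
#'
#' @param scene An [eo_scene()].
#' @param names Which layers, default [index_names()].
#' @return Named list of `index_raster`s.
#' @export
compute_all_indices <- function(scene, names = index_names()) {
  tc <- NULL
  out <- list()
  for (nm in names) {
    if (nm %in% c("TCB", "TCG", "TCW")) {
      if (is.null(tc)) tc <- tasseled_cap(scene)
      out[[nm]] <- tc[[nm]]
    } else {
      out[[nm]] <- compute_index(scene, nm)
    }
  }
  out
}
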