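# Raster and survey-table file interchange.
#
# Rasters are written as TIFF (32-bit float samples) with a JSON sidecar
# (`<path>.json`) carrying the grid geometry (pixel size, NW origin, CRS
# label, pixel-centre convention), band names, nodata handling and the
# per-band offset/scale used to map values into the TIFF's [0, 1] sample
# range. Integer rasters round-trip exactly; float rasters to well under
# 1e-7 at index/reflectance scale. Masked (NA) pixels are encoded in a
# dedicated mask sample.

#' Write a raster (single- or multi-band) with grid metadata
#'
#' @param layers A matrix, or a named list of matrices on one grid.
#' @param path Output path (`.tif`); a `.tif.json` sidecar is written too.
#' @param grid A [grid_spec()] (optional; a default unit grid is recorded
#'   if absent).
#' @param integer Store as integers (exact round trip for class codes).
#' @return `path`, invisibly.
#' @export
write_raster <- function(layers, path, grid = NULL, integer = FALSE) {
  if (is.matrix(layers)) layers <- list(band1 = layers)
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1) stop("band-count mismatch: bands on different grids")
  nr <- dims[[1]][1]; nc <- dims[[1]][2]
  grid <- grid %||% grid_spec(nr, nc, px = 1)
  nb <- length(layers)
  pages <- vector("list", nb) # one grey+alpha page per band (value + mask)
  meta_bands <- vector("list", nb)
  for (i in seq_len(nb)) {
    v <- layers[[i]]
    ok <- is.finite(v)
    lo <- if (any(ok)) min(v[ok]) else 0
    hi <- if (any(ok)) max(v[ok]) else 1
    scale <- max(hi - lo, if (integer) 1 else .Machine$double.eps)
    enc <- (v - lo) / scale
    enc[!ok] <- 0
    pages[[i]] <- array(c(enc, ok * 1), c(nr, nc, 2))
    meta_bands[[i]] <- list(name = names(layers)[i] %||% paste0("band", i),
                            offset = lo, scale = scale, integer = integer)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  meta <- list(
    format = "optihab-raster-1",
    nrow = nr, ncol = nc, px = grid$px, xmin = grid$xmin, ymax = grid$ymax,
    crs = grid$crs, convention = "row 1 = north edge; pixel-centre coords",
    bands = meta_bands
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster written by [write_raster()]
#'
#' @param path Path to the `.tif` file (sidecar `.tif.json` must exist).
#' @return List with `layers` (named list of matrices, `NA` where masked)
#'   and `grid` ([grid_spec()]).
#' @export
read_raster <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing raster metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  # grey+alpha pages trip a benign libtiff ExtraSamples notice
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE))
  bands <- meta$bands
  nb <- nrow(bands)
  if (length(pages) != nb) stop("band-count mismatch with manifest")
  layers <- vector("list", nb)
  for (i in seq_len(nb)) {
    arr <- pages[[i]]
    v <- arr[, , 1] * bands$scale[i] + bands$offset[i]
    if (isTRUE(bands$integer[i])) v <- round(v)
    v[arr[, , 2] < 0.5] <- NA
    layers[[i]] <- if (isTRUE(bands$integer[i])) {
      matrix(as.integer(v), meta$nrow, meta$ncol)
    } else v
  }
  names(layers) <- bands$name
  list(layers = layers,
       grid = grid_spec(meta$nrow, meta$ncol, px = meta$px,
                        xmin = meta$xmin, ymax = meta$ymax, crs = meta$crs))
}

#' Write / read survey tables
#'
#' Plain CSV with the documented column schemas (trapline:
#' `line_id, x, y, habitat, trap_type, night, captures, accessible`;
#' transect: `transect_id, interval, x, y, presence`).
#'
#' @param table data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_survey_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write a pipeline configuration
#'
#' Human-readable nested YAML carrying all generator and model parameters
#' plus the master seed; see [demo_config()] for the schema.
#'
#' @param config Configuration list.
#' @param path YAML path.
#' @return `path` (write) or the configuration list (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
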