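#' Regular raster grid specification
#'
#' All rasters in optihab are plain numeric (or integer) matrices on a shared
#' regular grid of square pixels in a projected, metre-based coordinate
#' system. A `grid_spec` records the grid geometry: matrix row 1 is the
#' northern edge, column 1 the western edge, and coordinates follow the
#' pixel-centre convention (the centre of pixel `[1, 1]` is at
#' `(xmin + px/2, ymax - px/2)`).
#'
#' @param nrow,ncol Grid dimensions (pixels).
#' @param px Pixel size in metres (square pixels).
#' @param xmin,ymax Coordinates of the grid's north-west corner (metres).
#' @param crs Free-text label for the coordinate reference system.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrow, ncol, px = 30, xmin = 0, ymax = nrow * px,
                      crs = "local metric CRS") {
  if (nrow < 1 || ncol < 1) stop("grid dimensions must be positive")
  if (px <= 0) stop("pixel size must be positive")
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol), px = px,
         xmin = xmin, ymax = ymax, crs = crs),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, %g m, origin NW (%g, %g), %s\n",
              x$nrow, x$ncol, x$px, x$xmin, x$ymax, x$crs))
  invisible(x)
}

#' Convert map coordinates to (row, col) pixel indices
#'
#' Points are assigned to the pixel containing them; points exactly on a
#' shared pixel edge belong to the pixel to the south/east of the edge,
#' except along the grid's outer boundary which is inclusive.
#'
#' @param grid A [grid_spec()].
#' @param x,y Numeric vectors of map coordinates (metres).
#' @return Integer matrix with columns `row`, `col`; off-grid points give NA.
#' @export
xy_to_rowcol <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$px) + 1L
  row <- floor((grid$ymax - y) / grid$px) + 1L
  # points on the far boundary fall in the last pixel
  col[x == grid$xmin + grid$ncol * grid$px] <- grid$ncol
  row[y == grid$ymax - grid$nrow * grid$px] <- grid$nrow
  bad <- col < 1L | col > grid$ncol | row < 1L | row > grid$nrow
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Pixel-centre coordinates for (row, col) indices
#'
#' @param grid A [grid_spec()].
#' @param row,col Integer vectors of pixel indices.
#' @return Numeric matrix with columns `x`, `y`.
#' @export
rowcol_to_xy <- function(grid, row, col) {
  cbind(x = grid$xmin + (col - 0.5) * grid$px,
        y = grid$ymax - (row - 0.5) * grid$px)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("nrow", "ncol", "px", "xmin", "ymax")],
                   b[c("nrow", "ncol", "px", "xmin", "ymax")]))
}
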