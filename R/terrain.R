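#' Slope and aspect from a DEM (Horn's method)
#'
#' Eight-neighbour finite differences (Horn 1981) on a square-pixel DEM.
#' Slope is returned in degrees; aspect in compass degrees clockwise from
#' north, pointing in the direction of steepest descent. Flat cells
#' (zero gradient) carry the aspect sentinel `-1`. Edge cells use clamped
#' (edge-replicated) neighbourhoods.
#'
#' @param dem Elevation matrix (m), at least 3x3.
#' @param px Pixel size (m).
#' @return List with matrices `slope` (degrees) and `aspect` (degrees, or
#'   `-1` where flat).
#' @export
terrain_derivatives <- function(dem, px = 30) {
  if (nrow(dem) < 3 || ncol(dem) < 3) stop("DEM must be at least 3x3")
  nr <- nrow(dem); nc <- ncol(dem)
  # clamped (replicated) border padding
  z <- dem[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  nw <- z[i - 1, j - 1]; n_ <- z[i - 1, j]; ne <- z[i - 1, j + 1]
  w_ <- z[i, j - 1];                       e_ <- z[i, j + 1]
  sw <- z[i + 1, j - 1]; s_ <- z[i + 1, j]; se <- z[i + 1, j + 1]
  dzdx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * px) # east +
  dzdy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * px) # north +
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # steepest-descent direction (-dzdx, -dzdy) as a compass bearing
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[slope == 0] <- -1
  list(slope = slope, aspect = aspect)
}
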