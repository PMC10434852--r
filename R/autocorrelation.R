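#' Moran's I with a permutation test
#'
#' Global Moran's I with binary distance-band weights
#' (`w_ij = 1` iff `0 < d_ij <= radius`), row-unstandardized:
#' `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `W = sum_ij w_ij`. The null expectation is `E[I] = -1/(n-1)`; the
#' p-value comes from random permutations of the values over the locations,
#' two-sided on `|I - E[I]|` with the observed statistic included in the
#' reference set.
#'
#' @param values Numeric vector (one value per unit).
#' @param coords Two-column matrix/data.frame of unit coordinates (m).
#' @param radius Neighbourhood distance band (m), default 1500.
#' @param n_permutations Number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return List with `I`, `expected`, `p`, `n`, `n_pairs`, `radius`.
#' @export
morans_i <- function(values, coords, radius = 1500, n_permutations = 999,
                     seed = NULL) {
  coords <- as.matrix(coords)
  n <- length(values)
  if (n < 4) stop("need at least 4 units")
  if (stats::sd(values) == 0) stop("Moran's I is undefined for constant values")
  d <- as.matrix(stats::dist(coords))
  w <- (d > 0 & d <= radius) * 1
  W <- sum(w)
  if (W == 0) stop("no neighbour pairs within the distance band")
  moran_stat <- function(x) {
    z <- x - mean(x)
    (n / W) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
  }
  I <- moran_stat(values)
  expected <- -1 / (n - 1)
  p <- NA_real_
  if (n_permutations > 0) {
    perm <- with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(i) moran_stat(sample(values)), 0)
    })
    p <- (1 + sum(abs(perm - expected) >= abs(I - expected))) /
      (n_permutations + 1)
  }
  list(I = I, expected = expected, p = p, n = n, n_pairs = W / 2,
       radius = radius)
}

#' Empirical semivariogram
#'
#' `gamma(h) = (1 / (2 N_h)) * sum over pairs in bin h of (x_i - x_j)^2`,
#' over distance bins of width `bin_width` up to `max_dist` (default: half
#' the maximum pair distance, the usual rule of thumb).
#'
#' @param values Numeric vector.
#' @param coords Two-column coordinates (m).
#' @param bin_width Lag bin width (m), > 0.
#' @param max_dist Largest lag considered.
#' @return data.frame with `lag` (bin centre), `gamma`, `n_pairs`; empty
#'   bins carry `gamma = NA`.
#' @export
empirical_semivariogram <- function(values, coords, bin_width = 500,
                                    max_dist = NULL) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (length(values) < 2) stop("need at least 2 units")
  coords <- as.matrix(coords)
  d <- stats::dist(coords)
  g <- stats::dist(matrix(values)) # |x_i - x_j| over the same pair order
  max_dist <- max_dist %||% (max(d) / 2)
  breaks <- seq(0, max_dist + bin_width, by = bin_width)
  bin <- cut(as.vector(d), breaks = breaks, include.lowest = FALSE)
  sq <- as.vector(g)^2
  n_pairs <- as.vector(table(bin))
  gamma <- as.vector(tapply(sq, bin, function(v) sum(v) / (2 * length(v))))
  data.frame(lag = (breaks[-1] + breaks[-length(breaks)]) / 2,
             gamma = gamma, n_pairs = n_pairs)
}
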