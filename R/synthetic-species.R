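# Species ground truth and survey observation generators. These encode the
# known abundance-covariate relationships that feature selection and the
# species distribution models must recover.

#' Specify a species' true dependence on landscape covariates
#'
#' The latent abundance surface is
#' `A(x) = exp(baseline + sum(coef * z(covariate(x))))`, with covariates
#' z-scored over land pixels. Trapline captures and transect presence are
#' generated from `A` with the nuisance effects below.
#'
#' @param species Species label.
#' @param terms Named numeric vector: coefficient per covariate name.
#' @param baseline Baseline log abundance (log expected captures per
#'   accessible trap-night at average covariates).
#' @param beta_type Log rate ratio of big (`bbbt`) vs small (`sbbt`)
#'   break-back traps.
#' @param beta_night Log rate trend per additional control night (night 1 is
#'   the reference).
#' @param trapline_sd S.d. of the trapline-level random intercept (>= 0).
#' @param transect_a,transect_b Intercept and slope of the logistic model for
#'   per-interval presence: `P(presence) = plogis(a + b * A)`.
#' @return Object of class `species_effect_spec`.
#' @export
species_effect_spec <- function(species, terms, baseline = log(0.05),
                                beta_type = 0.7, beta_night = -0.15,
                                trapline_sd = 0.3,
                                transect_a = -2, transect_b = 2) {
  if (trapline_sd < 0) stop("trapline_sd must be >= 0")
  if (length(terms) && is.null(names(terms))) stop("terms must be named")
  structure(list(species = species, terms = terms, baseline = baseline,
                 beta_type = beta_type, beta_night = beta_night,
                 trapline_sd = trapline_sd,
                 transect_a = transect_a, transect_b = transect_b),
            class = "species_effect_spec")
}

#' Latent abundance surface from named covariate rasters
#'
#' @param truth A `landscape_truth` (supplies the land mask: pixels that are
#'   not water or snow).
#' @param features Named list of covariate matrices.
#' @param spec A [species_effect_spec()].
#' @return Matrix of `A(x) >= 0`.
#' @export
generate_species_truth <- function(truth, features, spec) {
  missing_cov <- setdiff(names(spec$terms), names(features))
  if (length(missing_cov)) {
    stop("unknown covariate(s) in species spec: ",
         paste(missing_cov, collapse = ", "))
  }
  land <- !(truth$landcover %in% truth$legend[c("water", "snow")])
  eta <- matrix(spec$baseline, nrow(truth$landcover), ncol(truth$landcover))
  for (nm in names(spec$terms)) {
    f <- features[[nm]]
    z <- (f - mean(f[land], na.rm = TRUE)) /
      max(stats::sd(f[land], na.rm = TRUE), .Machine$double.eps)
    z[is.na(z)] <- 0 # masked covariate pixels carry no anomaly
    eta <- eta + spec$terms[[nm]] * z
  }
  A <- exp(eta)
  if (!all(is.finite(A))) stop("non-finite abundance surface")
  A
}

#' Simulate a trapline survey
#'
#' Trapline sites are sampled stratified by land-cover class over trappable
#' land (not water/snow), in proportion to class area. Each line runs
#' `nights` nights with 25 traps of one kind (`sbbt`/`bbbt`, alternated
#' within strata). Nightly captures are
#' `min(Poisson(accessible * A(x) * exp(beta_type*I[bbbt] +
#' beta_night*(night-1) + u_line)), accessible)` with
#' `u_line ~ N(0, trapline_sd^2)`. Traps are reset every morning, so a
#' night's accessible count is the number of operational traps that night
#' (free traps plus traps that captured the target species); a small
#' per-night loss probability `trap_loss` (theft/damage) makes the effort
#' offset vary. Deterministic given `seed`.
#'
#' @param truth A `landscape_truth`.
#' @param abundance Latent abundance matrix from [generate_species_truth()].
#' @param n_traplines Number of traplines (>= 1).
#' @param spec A [species_effect_spec()].
#' @param nights Nights per line (default 3).
#' @param traps_per_line Traps per line (default 25).
#' @param trap_loss Per-trap per-night loss probability (default 0.03).
#' @param seed Integer RNG seed (required).
#' @return data.frame with one row per (line, night): `line_id`, `x`, `y`,
#'   `habitat`, `trap_type`, `night`, `captures`, `accessible`, plus the
#'   latent `true_abundance` and `u_line` columns for ground-truth checks.
#' @export
generate_trapline_survey <- function(truth, abundance, n_traplines, spec,
                                     nights = 3, traps_per_line = 25,
                                     trap_loss = 0.03, seed) {
  if (n_traplines < 1) stop("n_traplines must be >= 1")
  if (missing(seed)) stop("seed is required")
  legend <- truth$legend
  lc <- truth$landcover
  trappable <- setdiff(names(legend), c("water", "snow"))
  with_seed(seed, {
    # stratified allocation proportional to class area (>= 1 where present)
    areas <- vapply(trappable, function(cl) sum(lc == legend[[cl]]), 0L)
    present <- trappable[areas > 0]
    alloc <- pmax(1L, round(areas[present] / sum(areas[present]) * n_traplines))
    while (sum(alloc) > n_traplines) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
    while (sum(alloc) < n_traplines) alloc[which.max(areas[present])] <- alloc[which.max(areas[present])] + 1L
    rows <- list()
    id <- 0L
    for (k in seq_along(present)) {
      cl <- present[k]
      cells <- which(lc == legend[[cl]])
      pick <- cells[sample.int(length(cells), alloc[k], replace = alloc[k] > length(cells))]
      for (cell in pick) {
        id <- id + 1L
        rc <- arrayInd(cell, dim(lc))
        xy <- rowcol_to_xy(truth$grid, rc[1], rc[2])
        u <- stats::rnorm(1, 0, spec$trapline_sd)
        trap_type <- if (id %% 2L == 0L) "bbbt" else "sbbt"
        a_line <- abundance[cell]
        free <- traps_per_line
        for (n in seq_len(nights)) {
          accessible <- free
          lam <- accessible * a_line *
            exp(spec$beta_type * (trap_type == "bbbt") +
                  spec$beta_night * (n - 1) + u)
          captures <- min(stats::rpois(1, lam), accessible)
          rows[[length(rows) + 1L]] <- data.frame(
            line_id = sprintf("L%03d", id), x = xy[, "x"], y = xy[, "y"],
            habitat = cl, trap_type = trap_type, night = n,
            captures = captures, accessible = accessible,
            true_abundance = a_line, u_line = u)
          lost <- stats::rbinom(1, free, trap_loss)
          free <- free - lost
          if (free < 1L) free <- 1L
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a transect survey
#'
#' Transects are placed in open habitat (grassland, arable, bare): a random
#' start pixel and heading define `intervals` interval midpoints spaced
#' `pace_m * 10` m apart (default pace 0.8 m, so 10 paces = 8 m). Each
#' interval is scored present with probability
#' `plogis(transect_a + transect_b * A(x_interval))`. Transects that would
#' run off-grid are redrawn (up to 200 attempts each). Deterministic given
#' `seed`.
#'
#' @param truth A `landscape_truth`.
#' @param abundance Latent abundance matrix.
#' @param n_transects Number of transects.
#' @param spec A [species_effect_spec()].
#' @param intervals Intervals per transect (default 20).
#' @param pace_m Metres per pace (default 0.8).
#' @param seed Integer RNG seed (required).
#' @return data.frame with one row per interval: `transect_id`, `interval`,
#'   `x`, `y`, `presence` (0/1), `true_abundance`.
#' @export
generate_transect_survey <- function(truth, abundance, n_transects, spec,
                                     intervals = 20, pace_m = 0.8, seed) {
  if (missing(seed)) stop("seed is required")
  legend <- truth$legend
  lc <- truth$landcover
  open_cells <- which(lc %in% legend[c("grassland", "arable", "bare")])
  if (length(open_cells) == 0) stop("no open-habitat pixels for transects")
  step <- pace_m * 10
  with_seed(seed, {
    rows <- list()
    for (tr in seq_len(n_transects)) {
      for (attempt in 1:200) {
        cell <- open_cells[sample.int(length(open_cells), 1)]
        rc <- arrayInd(cell, dim(lc))
        start <- rowcol_to_xy(truth$grid, rc[1], rc[2])
        heading <- stats::runif(1, 0, 2 * pi)
        xs <- start[, "x"] + (seq_len(intervals) - 1) * step * cos(heading)
        ys <- start[, "y"] + (seq_len(intervals) - 1) * step * sin(heading)
        rcs <- xy_to_rowcol(truth$grid, xs, ys)
        if (!anyNA(rcs)) break
        if (attempt == 200) stop("could not place transect inside the grid")
      }
      a <- abundance[rcs]
      p <- stats::plogis(spec$transect_a + spec$transect_b * a)
      pres <- stats::rbinom(intervals, 1, p)
      rows[[length(rows) + 1L]] <- data.frame(
        transect_id = sprintf("T%03d", tr), interval = seq_len(intervals),
        x = xs, y = ys, presence = pres, true_abundance = a)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
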