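# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a stage seed from a master seed
#'
#' One master seed is fanned out to every stochastic stage of the pipeline by
#' hashing the stage name into an offset. The derivation is a fixed integer
#' recurrence over the stage name's character codes (no external hash
#' dependency), keeps results in `[1, 2^31 - 2]`, and is stable across
#' platforms and R sessions.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @return A single integer seed.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(length(stage) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Gaussian-blur a matrix with a separable kernel (sd in pixels), with
# edge renormalisation so the border is a weighted mean of in-grid values.
smooth_matrix <- function(m, sd_px) {
  if (sd_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_px))
  k <- stats::dnorm(-half:half, sd = sd_px)
  k <- k / sum(k)
  conv1 <- function(mat, kern) {
    # convolve along rows (i.e. down each column) with zero padding
    nr <- nrow(mat)
    out <- matrix(0, nr, ncol(mat))
    wt <- matrix(0, nr, ncol(mat))
    h <- (length(kern) - 1L) / 2L
    for (o in -h:h) {
      src <- (1:nr) + o
      ok <- src >= 1 & src <= nr
      w <- kern[o + h + 1L]
      out[ok, ] <- out[ok, ] + w * mat[src[ok], ]
      wt[ok, ] <- wt[ok, ] + w
    }
    out / wt
  }
  t(conv1(t(conv1(m, k)), k))
}

# Vectorised row-wise quantiles with NA handling (linear interpolation
# between closest order statistics, i.e. stats::quantile type 7).
row_quantiles <- function(x, probs) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  sorted <- t(apply(x, 1, sort, na.last = TRUE))
  if (ncol(x) == 1L) sorted <- matrix(sorted, ncol = 1L) # apply drops dim
  k <- rowSums(!is.na(x))
  out <- matrix(NA_real_, n, length(probs),
                dimnames = list(NULL, paste0("p", probs * 100)))
  idx <- seq_len(n)
  for (j in seq_along(probs)) {
    h <- (k - 1) * probs[j] + 1
    lo <- pmax(floor(h), 1)
    hi <- pmin(ceiling(h), pmax(k, 1))
    vlo <- sorted[cbind(idx, lo)]
    vhi <- sorted[cbind(idx, hi)]
    v <- vlo + (h - lo) * (vhi - vlo)
    v[k == 0] <- NA_real_
    out[, j] <- v
  }
  out
}

# z-score a vector, guarding the degenerate constant case.
zscore <- function(v, center = mean(v, na.rm = TRUE), scale = stats::sd(v, na.rm = TRUE)) {
  if (!is.finite(scale) || scale == 0) scale <- 1
  (v - center) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a
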