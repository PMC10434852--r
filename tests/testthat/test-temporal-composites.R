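# independent brute-force oracle: explicit sort + linear interpolation
oracle_quantile <- function(v, p) {
  v <- sort(v[!is.na(v)])
  k <- length(v)
  if (k == 0) return(NA_real_)
  h <- (k - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

series_metrics <- function(values_list, min_obs = 3) {
  idx <- lapply(values_list, function(v) {
    m <- matrix(v, 1, 1)
    structure(list(name = "X", values = m, valid = !is.na(m)),
              class = "index_raster")
  })
  percentile_metrics(idx, min_obs = min_obs)
}

test_that("constant series collapses to the constant with zero ranges", {
  pm <- series_metrics(as.list(rep(0.4, 6)))
  for (ln in c("p5", "p25", "p50", "p75", "p95")) {
    expect_equal(pm$layers[[ln]][1, 1], 0.4)
  }
  for (ln in c("range", "r75_25", "r90_10", "r95_5")) {
    expect_equal(pm$layers[[ln]][1, 1], 0)
  }
})

test_that("the decile series reproduces hand-interpolated percentiles", {
  pm <- series_metrics(as.list(seq(0.1, 1.0, by = 0.1)))
  expect_equal(pm$layers$p50[1, 1], 0.55)
  expect_equal(pm$layers$p90[1, 1], 0.91)
  expect_equal(pm$layers$r90_10[1, 1], 0.91 - 0.19)
})

test_that("metrics equal the brute-force oracle on random masked series", {
  set.seed(31)
  for (i in 1:200) {
    k <- sample(3:14, 1)
    v <- runif(k)
    v[runif(k) < 0.25] <- NA
    pm <- series_metrics(as.list(v), min_obs = 1)
    if (sum(!is.na(v)) == 0) next
    for (p in c(0.05, 0.25, 0.5, 0.9, 0.95)) {
      lname <- paste0("p", p * 100)
      expect_equal(pm$layers[[lname]][1, 1], oracle_quantile(v, p),
                   tolerance = 1e-12)
    }
    expect_equal(pm$layers$range[1, 1], diff(range(v, na.rm = TRUE)))
  }
})

test_that("percentile monotonicity and non-negative ranges hold collection-wide", {
  ndvi <- lapply(fx_scenes, compute_index, "NDVI")
  pm <- percentile_metrics(ndvi)
  ok <- !is.na(pm$layers$p5)
  expect_true(all(diff_ok <- pm$layers$p5[ok] <= pm$layers$p10[ok]))
  expect_true(all(pm$layers$p10[ok] <= pm$layers$p25[ok]))
  expect_true(all(pm$layers$p25[ok] <= pm$layers$p50[ok]))
  expect_true(all(pm$layers$p50[ok] <= pm$layers$p75[ok]))
  expect_true(all(pm$layers$p75[ok] <= pm$layers$p90[ok]))
  expect_true(all(pm$layers$p90[ok] <= pm$layers$p95[ok]))
  for (ln in c("range", "r75_25", "r90_10", "r95_5")) {
    expect_true(all(pm$layers[[ln]][ok] >= 0), info = ln)
  }
  # pixels with too few valid observations are masked
  expect_true(all(is.na(pm$layers$p50[pm$count < pm$min_obs])))
})

test_that("metrics are invariant to scene order", {
  ndvi <- lapply(fx_scenes, compute_index, "NDVI")
  a <- percentile_metrics(ndvi)
  b <- percentile_metrics(rev(ndvi))
  expect_equal(a$layers, b$layers)
})

test_that("mask_scene composes masks and drives the valid count", {
  sc <- fx_clear
  m <- matrix(TRUE, 60, 60)
  expect_identical(mask_scene(sc, m), sc)
  none <- mask_scene(sc, !m)
  pm <- percentile_metrics(list(compute_index(none, "NDVI")), min_obs = 1)
  expect_true(all(pm$count == 0))
  expect_true(all(is.na(pm$layers$p50)))
  half <- m; half[, 1:30] <- FALSE
  masked <- mask_scene(sc, half)
  pm2 <- percentile_metrics(list(compute_index(masked, "NDVI"),
                                 compute_index(sc, "NDVI")), min_obs = 1)
  expect_true(all(pm2$count[, 1:30] == 1) && all(pm2$count[, 31:60] == 2))
  expect_error(mask_scene(sc, matrix(TRUE, 2, 2)), "grid")
})

test_that("median composite equals the p50 path and the sort oracle", {
  one <- median_composite(list(fx_clear))
  expect_equal(one$red, fx_clear$bands$red)
  # three-value example
  vals <- c(0.2, 0.4, 0.9)
  scs <- lapply(vals, function(v) {
    eo_scene(lapply(stats::setNames(nm = c("blue", "green", "red", "nir",
                                           "swir1", "swir2")),
                    function(b) matrix(v, 2, 2)),
             valid = matrix(TRUE, 2, 2), doy = 1)
  })
  expect_equal(median_composite(scs)$nir, matrix(0.4, 2, 2))
  # definitional equivalence on the fixture collection
  comp <- median_composite(fx_scenes)
  red_idx <- lapply(fx_scenes, function(s) {
    v <- s$bands$red; v[!s$valid] <- NA
    structure(list(name = "red", values = v, valid = s$valid),
              class = "index_raster")
  })
  expect_equal(comp$red, percentile_metrics(red_idx, min_obs = 1)$layers$p50)
  expect_error(median_composite(list()), "empty")
})
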