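# brute-force focal oracle: double loop over pixels and candidate offsets
oracle_focal <- function(map, code, kernel_m, px = 30) {
  nr <- nrow(map); nc <- ncol(map)
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    hit <- 0; tot <- 0
    for (a in 1:nr) for (b in 1:nc) {
      if (px * sqrt((a - i)^2 + (b - j)^2) <= kernel_m) {
        tot <- tot + 1
        if (map[a, b] == code) hit <- hit + 1
      }
    }
    out[i, j] <- hit / tot
  }
  out
}

test_that("stack assembly yields the 12 documented layers with mask propagation", {
  comp <- median_composite(fx_scenes)
  ndvi <- percentile_metrics(lapply(fx_scenes, compute_index, "NDVI"),
                             min_obs = 2)
  terr <- terrain_derivatives(fx_truth$dem)
  st <- assemble_stack(comp, ndvi, fx_truth$dem, terr)
  expect_length(st$layers, 12)
  expect_identical(st$manifest,
                   c("median_blue", "median_green", "median_red", "median_nir",
                     "median_swir1", "median_swir2", "ndvi_p10", "ndvi_p90",
                     "ndvi_r90_10", "elevation", "slope", "aspect"))
  masked_any <- Reduce(`|`, lapply(st$layers, is.na))
  expect_identical(st$valid, !masked_any)
})

test_that("classification recovers perfectly separable classes and is deterministic", {
  # two classes with disjoint feature ranges
  lc <- matrix(1L, 30, 30); lc[, 16:30] <- 6L
  truth2 <- fx_truth
  truth2$landcover <- lc
  truth2$grid <- grid_spec(30, 30)
  truth2$dem <- fx_truth$dem[1:30, 1:30]
  sep <- matrix(0, 30, 30); sep[, 16:30] <- 10
  st <- structure(list(layers = list(f1 = sep, f2 = -sep),
                       manifest = c("f1", "f2"),
                       valid = matrix(TRUE, 30, 30)),
                  class = "feature_stack")
  polys <- make_training_polygons(truth2, n_polys = 4, seed = 2)
  m1 <- classify_landcover(st, polys, n_per_class = 100, seed = 5)
  expect_identical(m1$map, lc)
  m2 <- classify_landcover(st, polys, n_per_class = 100, seed = 5)
  expect_identical(m1$map, m2$map)
})

test_that("confusion matrix reproduces hand-computed accuracies", {
  # toy 2-class map with known confusion counts [[40,10],[5,45]]
  map <- matrix(c(rep(1L, 40), rep(2L, 10), rep(2L, 45), rep(1L, 5)), 10, 10)
  ref <- data.frame(row = rep(1:10, 10), col = rep(1:10, each = 10),
                    code = c(rep(1L, 50), rep(2L, 50)))
  cm <- confusion_matrix(map, ref)
  expect_equal(cm$overall, 0.85)
  expect_equal(unname(rowSums(cm$matrix)), c(50, 50))
  # identity map scores 100%
  ref2 <- data.frame(row = 1:10, col = 1:10, code = map[cbind(1:10, 1:10)])
  cm2 <- confusion_matrix(map, ref2)
  expect_equal(cm2$overall, 1)
  expect_equal(sum(cm2$matrix) - sum(diag(cm2$matrix)), 0)
  expect_error(confusion_matrix(map, data.frame(row = 99, col = 1, code = 1)),
               "off-grid")
})

test_that("focal proportions match the brute-force oracle on a random map", {
  set.seed(77)
  map <- matrix(sample(c(1L, 2L, 3L), 25 * 25, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)), 25, 25)
  for (k in seq(50, 500, by = 50)) {
    got <- focal_proportion(map, 1L, k)
    expect_equal(got, oracle_focal(map, 1L, k), tolerance = 1e-12,
                 info = paste("kernel", k))
  }
})

test_that("focal proportion saturates, and the 50 m kernel spans 9 centres", {
  uni <- matrix(1L, 10, 10)
  expect_true(all(focal_proportion(uni, 1L, 100) == 1))
  # single target pixel: with 30 m pixels every one of the 3x3 neighbours'
  # centres lies within 50 m (diagonal distance 42.4 m), so the focal value
  # at the target is 1/9; the brute-force oracle agrees
  map <- matrix(2L, 9, 9); map[5, 5] <- 1L
  got <- focal_proportion(map, 1L, 50)
  expect_equal(got[5, 5], 1 / 9)
  expect_equal(got, oracle_focal(map, 1L, 50), tolerance = 1e-12)
  expect_error(focal_proportion(map, 1L, 10), "at least one pixel")
})

test_that("tracked-class proportions are a partition bound and kernels converge", {
  props <- proportion_layers(fx_truth$landcover, kernels_m = c(50, 250, 500))
  total <- props$prop_grassland_50m + props$prop_woodland_50m +
    props$prop_arable_50m
  expect_true(all(total <= 1 + 1e-12))
  # growing kernels pull the local proportion toward the global fraction
  glob <- mean(fx_truth$landcover == 1L)
  err500 <- mean(abs(props$prop_grassland_500m - glob))
  err50 <- mean(abs(props$prop_grassland_50m - glob))
  expect_lt(err500, err50)
})

test_that("shuffled training labels drop accuracy to chance level", {
  comp <- median_composite(fx_scenes)
  ndvi <- percentile_metrics(lapply(fx_scenes, compute_index, "NDVI"),
                             min_obs = 2)
  terr <- terrain_derivatives(fx_truth$dem)
  st <- assemble_stack(comp, ndvi, fx_truth$dem, terr)
  polys <- make_training_polygons(fx_truth, n_polys = 8, seed = 12)
  shuffled <- polys
  set.seed(99)
  shuffled$code <- sample(shuffled$code)
  m <- classify_landcover(st, shuffled, n_per_class = 300, seed = 13)
  ref <- sample_reference_points(fx_truth, 40, seed = 14)
  acc <- confusion_matrix(m, ref)$overall
  expect_lt(acc, 0.45) # chance is ~1/8 for balanced classes
})
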