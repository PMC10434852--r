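test_that("feature extraction matches manual pixel lookup", {
  g <- fx_truth$grid
  set.seed(17)
  rows <- sample(60, 10); cols <- sample(60, 10)
  xy <- rowcol_to_xy(g, rows, cols)
  obs <- data.frame(unit = paste0("u", 1:10), x = xy[, "x"], y = xy[, "y"],
                    value = rnorm(10))
  tab <- build_feature_table(fx_features, obs, g)
  expect_equal(tab$NDVI_p90,
               fx_features$NDVI_p90[cbind(rows, cols)])
  expect_equal(tab$elevation, fx_features$elevation[cbind(rows, cols)])
  # constant raster gives a constant column
  tab2 <- build_feature_table(list(k = matrix(4, 60, 60)), obs, g)
  expect_true(all(tab2$k == 4))
  expect_error(build_feature_table(fx_features,
                                   transform(obs, x = x + 1e6), g),
               "outside the grid")
  # units on masked pixels are dropped and counted
  masked <- fx_features
  masked$NDVI_p90[cbind(rows[1:3], cols[1:3])] <- NA
  tab3 <- build_feature_table(masked, obs, g)
  expect_equal(nrow(tab3), 7)
  expect_equal(attr(tab3, "n_dropped"), 3)
})

test_that("LOOCV hits R2 limits and never touches the held-out row", {
  set.seed(19)
  n <- 30
  X <- data.frame(x1 = runif(n), x2 = runif(n))
  tab <- cbind(data.frame(unit = 1:n, response = X$x1 * 3 + rnorm(n, 0, 0.05)), X)
  attr(tab, "covariates") <- c("x1", "x2")
  cv <- loocv(tab, rf_params(n_trees = 100), seed = 23)
  expect_gt(cv$r2, 0.8)
  expect_lte(cv$r2, 1)
  expect_equal(length(cv$predicted), n)
  # changing a held-out row's response cannot change its own prediction
  tab2 <- tab
  tab2$response[1] <- tab2$response[1] + 100
  attr(tab2, "covariates") <- c("x1", "x2")
  cv2 <- loocv(tab2, rf_params(n_trees = 100), seed = 23)
  expect_identical(cv$predicted[1], cv2$predicted[1])
  expect_error(loocv(transform(tab, response = 1), rf_params(), seed = 1),
               "constant response")
})

test_that("tuning returns the LOOCV argmax with deterministic tie-breaks", {
  set.seed(29)
  n <- 25
  tab <- data.frame(unit = 1:n, x1 = runif(n))
  tab$response <- 2 * tab$x1 + rnorm(n, 0, 0.1)
  attr(tab, "covariates") <- "x1"
  single <- data.frame(n_trees = 50, min_leaf = 2, max_nodes = NA,
                       vps = NA, bag_fraction = 0.7)
  got <- tune_hyperparameters(tab, grid = single, seed = 31)
  expect_equal(got$best$n_trees, 50)
  expect_equal(got$best$min_leaf, 2)
  grid <- rbind(single, transform(single, n_trees = 100))
  got2 <- tune_hyperparameters(tab, grid = grid, seed = 31)
  expect_equal(max(got2$table$r2), got2$table$r2[1])
  # ordering rule: equal-R2 rows resolve toward fewer trees, smaller leaves
  tt <- data.frame(n_trees = c(200, 100, 100), min_leaf = c(1, 5, 1),
                   max_nodes = NA, vps = NA, bag_fraction = 0.7,
                   r2 = c(0.9, 0.9, 0.9))
  ord <- order(-tt$r2, tt$n_trees, tt$min_leaf)
  expect_equal(tt[ord[1], c("n_trees", "min_leaf")],
               data.frame(n_trees = 100, min_leaf = 1), ignore_attr = TRUE)
  expect_error(tune_hyperparameters(tab, grid = single[0, ], seed = 1),
               "empty")
})

test_that("prediction surfaces respect forest averaging bounds", {
  set.seed(37)
  n <- 40
  tab <- data.frame(unit = 1:n, a = runif(n), b = runif(n))
  tab$response <- 5 * tab$a + rnorm(n, 0, 0.1)
  attr(tab, "covariates") <- c("a", "b")
  rasters <- list(a = matrix(runif(400), 20, 20),
                  b = matrix(runif(400), 20, 20))
  fp <- fit_and_predict(tab, rf_params(), rasters, seed = 41)
  expect_true(all(fp$prediction >= min(tab$response) - 1e-9))
  expect_true(all(fp$prediction <= max(tab$response) + 1e-9))
  # constant covariates with full bagging collapse to the response mean
  const <- list(a = matrix(0.5, 5, 5), b = matrix(0.5, 5, 5))
  tabc <- data.frame(unit = 1:n, a = 0.5, b = 0.5,
                     response = tab$response)
  attr(tabc, "covariates") <- c("a", "b")
  fpc <- fit_and_predict(tabc, rf_params(bag_fraction = 1), const, seed = 43)
  expect_equal(unique(as.vector(fpc$prediction)), mean(tab$response),
               tolerance = 1e-9)
  expect_error(fit_and_predict(tab, rf_params(), rasters["a"], seed = 1),
               "missing covariate")
  # masked covariate pixels propagate to the prediction
  rasters$a[1, 1] <- NA
  fp2 <- fit_and_predict(tab, rf_params(), rasters, seed = 41)
  expect_true(is.na(fp2$prediction[1, 1]))
})

test_that("mean-threshold optimal habitat uses a strict boundary", {
  pred <- matrix(c(1, 2, 3, 4), 2, 2)
  oh <- optimal_habitat(pred, c(1, 2, 3))
  expect_equal(oh$threshold, 2)
  expect_equal(oh$optimal, matrix(c(0L, 0L, 1L, 1L), 2, 2))
  # raster equal to the threshold everywhere: nothing is optimal
  flat <- optimal_habitat(matrix(2, 3, 3), c(1, 2, 3))
  expect_true(all(flat$optimal == 0L))
  above <- optimal_habitat(matrix(9, 3, 3), c(1, 2, 3))
  expect_true(all(above$optimal == 1L))
  expect_error(optimal_habitat(pred, numeric(0)), "no training predictions")
})

test_that("area statistics convert pixel counts exactly", {
  m <- matrix(0L, 100, 100)
  m[seq_len(5000)] <- 1L
  st <- area_stats(m, px = 30)
  expect_equal(st$optimal_km2, 4.5)
  expect_equal(st$pct_total_land, 50)
  expect_equal(area_stats(matrix(0L, 5, 5))$optimal_km2, 0)
  expect_equal(area_stats(matrix(0L, 5, 5))$pct_total_land, 0)
  # masked pixels leave the percentage untouched
  m2 <- rbind(m, matrix(NA_integer_, 20, 100))
  expect_equal(area_stats(m2, px = 30)$pct_total_land, 50)
  expect_error(area_stats(m, px = 0), "positive")
})
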