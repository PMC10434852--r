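make_table <- function(n = 60, p = 10, k = 2, noise = 0.5, seed = 1,
                       permute = FALSE) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(X) <- paste0("v", sprintf("%02d", seq_len(p)))
  y <- rowSums(X[, seq_len(k), drop = FALSE]) + rnorm(n, 0, noise)
  if (permute) y <- sample(y)
  cbind(data.frame(unit = seq_len(n), response = y), X)
}

test_that("explicit permutation importance separates signal from noise", {
  tab <- make_table(n = 80, p = 4, k = 1, noise = 0.1, seed = 2)
  X <- tab[, paste0("v", sprintf("%02d", 1:4))]
  X$v04 <- 1 # constant column
  fit <- optihab:::fit_regression_forest(X, tab$response,
                                         rf_params(n_trees = 300),
                                         seed = 5, keep_inbag = TRUE)
  imp <- permutation_importance(fit, X, tab$response, n_repeats = 3, seed = 6)
  expect_gt(imp["v01"], 10 * max(abs(imp[c("v02", "v03")])))
  expect_identical(unname(imp["v04"]), 0) # permuting a constant changes nothing
  # ordering of informative vs noise is stable across seeds
  ranks <- vapply(1:5, function(s) {
    i <- permutation_importance(fit, X, tab$response, n_repeats = 2, seed = s)
    names(which.max(i))
  }, "")
  expect_true(all(ranks == "v01"))
  expect_error(permutation_importance(structure(list(), class = "randomForest"),
                                      X, tab$response),
               "keep.inbag")
})

test_that("permutation importance is deterministic given a seed", {
  tab <- make_table(n = 40, p = 5, k = 2, seed = 3)
  X <- tab[, grep("^v", names(tab))]
  fit <- optihab:::fit_regression_forest(X, tab$response,
                                         rf_params(n_trees = 200),
                                         seed = 7, keep_inbag = TRUE)
  a <- permutation_importance(fit, X, tab$response, n_repeats = 2, seed = 9)
  b <- permutation_importance(fit, X, tab$response, n_repeats = 2, seed = 9)
  expect_identical(a, b)
})

test_that("boruta confirms strong signal, rejects noise, and partitions", {
  tab <- make_table(n = 60, p = 12, k = 3, noise = 0.4, seed = 11)
  b <- boruta_select(tab, seed = 21)
  dec <- as.character(b$decision)
  expect_true(all(dec[1:3] %in% c("confirmed", "tentative_confirmed")))
  expect_gte(sum(dec[4:12] %in% c("rejected", "tentative_rejected")), 8)
  # decisions partition the covariates; hits never exceed iterations
  expect_length(b$decision, 12)
  expect_false(any(is.na(b$decision)))
  expect_true(all(b$hits <= b$iterations))
  # confirmed features sit above the shadow-max median
  med_shadow <- median(b$shadow_max_history)
  for (v in names(b$decision)[b$decision == "confirmed"]) {
    expect_gt(median(b$importance_history[, v], na.rm = TRUE), med_shadow)
  }
})

test_that("boruta is deterministic and invariant to column order", {
  tab <- make_table(n = 50, p = 8, k = 2, seed = 13)
  b1 <- boruta_select(tab, seed = 31)
  b2 <- boruta_select(tab, seed = 31)
  expect_identical(b1$decision, b2$decision)
  expect_identical(b1$hits, b2$hits)
  covs <- grep("^v", names(tab), value = TRUE)
  tab_perm <- tab[, c("unit", "response", rev(covs))]
  b3 <- boruta_select(tab_perm, seed = 31)
  expect_identical(b1$decision[covs], b3$decision[covs])
})

test_that("degenerate tables are refused", {
  tab <- make_table(n = 4, p = 6, seed = 15)
  expect_error(boruta_select(tab, seed = 1), "fewer than 5 units")
  tab1 <- make_table(n = 30, p = 1, k = 1, seed = 16)
  expect_error(boruta_select(tab1, seed = 1), "at least 2 covariates")
})
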