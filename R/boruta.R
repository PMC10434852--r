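# All-relevant (Boruta-style) feature selection for a continuous response,
# implemented from scratch over a random-forest regression backend.

#' Out-of-bag permutation importance
#'
#' For a fitted regression forest (built with `keep.inbag`), the importance
#' of a covariate is the mean increase in out-of-bag squared error when that
#' covariate's column is randomly permuted, averaged over `n_repeats`
#' independent permutations. Out-of-bag predictions are assembled from the
#' per-tree predictions restricted to trees that did not train on the row.
#' Permuting a constant column changes nothing, so its importance is
#' exactly zero. Deterministic given `seed`.
#'
#' @param model A `randomForest` regression fit with `keep.inbag = TRUE`.
#' @param X data.frame of covariates the model was trained on.
#' @param y Numeric response.
#' @param n_repeats Permutations per covariate (>= 1).
#' @param seed RNG seed.
#' @return Named numeric vector of importances (increase in OOB MSE).
#' @export
permutation_importance <- function(model, X, y, n_repeats = 5, seed = NULL) {
  if (is.null(model$inbag)) {
    stop("model must be fitted with keep.inbag = TRUE")
  }
  oob <- model$inbag == 0
  if (!any(oob)) stop("no out-of-bag observations")
  oob_pred <- function(Xq) {
    ind <- stats::predict(model, Xq, predict.all = TRUE)$individual
    rowSums(ind * oob) / pmax(rowSums(oob), 1)
  }
  base_mse <- mean((y - oob_pred(X))^2)
  with_seed(seed, {
    imp <- vapply(names(X), function(j) {
      mean(vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[[j]] <- X[[j]][sample.int(nrow(X))]
        if (identical(Xp[[j]], X[[j]])) return(0) # constant (or fixed) column
        mean((y - oob_pred(Xp))^2) - base_mse
      }, 0))
    }, 0)
    imp
  })
}

# scaled OOB permutation importance from the forest's native accounting
# (mean per-tree increase in OOB MSE / its standard error) — the same
# statistic as permutation_importance computed tree-wise in compiled code.
native_importance <- function(X, y, n_trees, seed) {
  fit <- with_seed(seed, {
    # the regression default mtry = p/3 (not sqrt(p)) so weak but relevant
    # covariates are evaluated in enough splits to register importance
    randomForest::randomForest(x = X, y = y, ntree = n_trees,
                               mtry = max(1L, floor(ncol(X) / 3)),
                               importance = TRUE)
  })
  # raw (unscaled) mean increase in OOB MSE: z-scaling inflates weak-but-
  # consistent null associations relative to the shadow maximum
  randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
}

#' Boruta all-relevant feature selection
#'
#' Iteratively compares each covariate's importance against "shadow"
#' covariates — independently permuted copies of the covariates — in a
#' joint random-forest regression. A covariate scores a hit in an iteration
#' when its importance exceeds the maximum shadow importance. The shadow
#' pool always spans all original covariates so the maximum-shadow
#' reference keeps constant strength as covariates are rejected.
#' After each iteration, two-sided binomial tests (success probability 0.5)
#' with Bonferroni correction over the original covariates confirm
#' covariates with significantly more hits than expected and reject those
#' with significantly fewer; rejected covariates are removed from subsequent
#' iterations. Covariates still undecided at `max_iter` are tentative and
#' are resolved by the "rough fix": tentative covariates whose median
#' importance over the iterations they participated in exceeds the median
#' of the per-iteration maximum shadow importances are confirmed, the rest
#' rejected (recorded as `tentative_confirmed` / `tentative_rejected`).
#' Deterministic given `seed`.
#'
#' @param table A [build_feature_table()] result, or any data.frame with a
#'   `response` column and covariate columns.
#' @param alpha Test level (default 0.01).
#' @param max_iter Maximum iterations (default 100).
#' @param n_trees Trees per iteration forest (default 500: selection
#'   stability over speed).
#' @param shadow_min Floor on the shadow-pool width (default 20): rejected
#'   covariates keep contributing permuted shadows until the pool would
#'   exceed this size.
#' @param seed Integer RNG seed (required).
#' @return Object of class `boruta_result`: list with `decision` (named
#'   factor: confirmed / rejected / tentative_confirmed /
#'   tentative_rejected), `selected` (covariates passed downstream), `hits`,
#'   `iterations`, `importance_history` (iterations x covariates),
#'   `shadow_max_history`, `alpha`, `seed`.
#' @export
boruta_select <- function(table, alpha = 0.01, max_iter = 100, n_trees = 500,
                          shadow_min = 20, seed) {
  if (missing(seed)) stop("seed is required")
  covs <- attr(table, "covariates") %||%
    setdiff(names(table), c("unit", "response"))
  X <- as.data.frame(table[, covs, drop = FALSE])
  y <- table$response
  if (length(covs) < 2) stop("need at least 2 covariates")
  if (nrow(X) < 5) stop("fewer than 5 units: selection would be unreliable")

  m <- length(covs)
  hits <- stats::setNames(integer(m), covs)
  iters_in <- stats::setNames(integer(m), covs)
  decision <- stats::setNames(rep("tentative", m), covs)
  imp_hist <- matrix(NA_real_, max_iter, m, dimnames = list(NULL, covs))
  shadow_max <- rep(NA_real_, max_iter)
  it <- 0L
  with_seed(seed, {
    while (it < max_iter && any(decision == "tentative")) {
      it <- it + 1L
      active <- names(decision)[decision != "rejected"]
      # shadows are fresh permuted copies of the remaining covariates,
      # padded with permuted copies of already-rejected covariates so the
      # pool never shrinks below `shadow_min`: a floor on the pool width
      # keeps the maximum-shadow reference competitive late in the run,
      # when covariates that merely share chance correlation with the
      # response would otherwise inflate their hit rates
      shadow_src <- active
      if (length(shadow_src) < shadow_min) {
        extra <- setdiff(names(X), active)
        shadow_src <- c(shadow_src,
                        extra[seq_len(min(length(extra),
                                          shadow_min - length(shadow_src)))])
      }
      while (length(shadow_src) < 5) shadow_src <- c(shadow_src, shadow_src)
      shadows <- as.data.frame(lapply(X[shadow_src], function(col) {
        col[sample.int(length(col))]
      }))
      names(shadows) <- paste0("shadow_", seq_along(shadow_src))
      joint <- cbind(X[active], shadows)
      imp <- native_importance(joint, y, n_trees,
                               seed = sample.int(.Machine$integer.max, 1))
      smax <- max(imp[names(shadows)])
      shadow_max[it] <- smax
      imp_hist[it, active] <- imp[active]
      undecided <- names(decision)[decision == "tentative"]
      hits[undecided] <- hits[undecided] + (imp[undecided] > smax)
      iters_in[active] <- iters_in[active] + 1L
      # two-sided binomial testing at p = 0.5 (one-sided tail in each
      # direction), Bonferroni-corrected over the m covariates
      for (v in undecided) {
        k <- hits[[v]]; n <- iters_in[[v]]
        p_hi <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
        p_lo <- stats::pbinom(k, n, 0.5)
        if (p_hi < alpha / m) decision[v] <- "confirmed"
        else if (p_lo < alpha / m) decision[v] <- "rejected"
      }
    }
    # rough fix for covariates still tentative at max_iter
    for (v in names(decision)[decision == "tentative"]) {
      med_v <- stats::median(imp_hist[, v], na.rm = TRUE)
      med_s <- stats::median(shadow_max[seq_len(it)], na.rm = TRUE)
      decision[v] <- if (is.finite(med_v) && med_v > med_s) {
        "tentative_confirmed"
      } else {
        "tentative_rejected"
      }
    }
  })
  selected <- names(decision)[decision %in% c("confirmed", "tentative_confirmed")]
  structure(
    list(decision = factor(decision,
                           levels = c("confirmed", "rejected",
                                      "tentative_confirmed",
                                      "tentative_rejected")),
         selected = selected, hits = hits, iterations = it,
         importance_history = imp_hist[seq_len(it), , drop = FALSE],
         shadow_max_history = shadow_max[seq_len(it)],
         alpha = alpha, seed = as.integer(seed)),
    class = "boruta_result"
  )
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("<boruta_result> %d iterations, alpha = %g\n", x$iterations,
              x$alpha))
  print(table(x$decision))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Importance ranking of selected covariates
#'
#' Ranks the selected covariates by explicit out-of-bag permutation
#' importance of a forest fitted on them alone (decreasing), for reporting
#' alongside the selection result.
#'
#' @param table A [build_feature_table()] result.
#' @param selected Covariate names (e.g. `boruta_result$selected`).
#' @param params An [rf_params()] for the ranking forest.
#' @param n_repeats Permutations per covariate.
#' @param seed RNG seed.
#' @return data.frame with `covariate` and `importance`, sorted decreasing.
#' @export
importance_ranking <- function(table, selected, params = rf_params(n_trees = 500),
                               n_repeats = 5, seed = NULL) {
  X <- as.data.frame(table[, selected, drop = FALSE])
  fit <- fit_regression_forest(X, table$response, params, seed = seed,
                               keep_inbag = TRUE)
  imp <- permutation_importance(fit, X, table$response, n_repeats = n_repeats,
                                seed = seed)
  data.frame(covariate = names(sort(imp, decreasing = TRUE)),
             importance = as.numeric(sort(imp, decreasing = TRUE)))
}
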