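#' Transect relative-abundance scores
#'
#' One transect unit is a block of 20 surveyed intervals; its score is the
#' number of intervals with a presence indicator for the species (0-20).
#' The unit's location is the mean of its interval coordinates.
#'
#' @param records data.frame with `transect_id`, `interval`, `x`, `y`,
#'   `presence` (0/1) — the schema written by [generate_transect_survey()].
#' @param intervals Required intervals per transect (default 20).
#' @param species Species label carried into the output.
#' @return data.frame of abundance observations: `unit`, `x`, `y`,
#'   `species`, `value` (integer score), `source = "transect"`.
#' @export
transect_scores <- function(records, intervals = 20, species = "species") {
  counts <- table(records$transect_id)
  if (any(counts != intervals)) {
    stop("each transect must have exactly ", intervals, " interval records")
  }
  if (!all(records$presence %in% c(0, 1))) stop("presence must be 0/1")
  agg <- stats::aggregate(cbind(value = presence) ~ transect_id,
                          data = records, FUN = sum)
  xy <- stats::aggregate(cbind(x, y) ~ transect_id, data = records, FUN = mean)
  out <- merge(agg, xy, by = "transect_id")
  data.frame(unit = out$transect_id, x = out$x, y = out$y,
             species = species, value = as.integer(out$value),
             source = "transect")
}

#' Poisson mixed model for trapline captures
#'
#' Fits `captures ~ trap_type + night + (1 | line) + offset(log(accessible))`
#' with a Poisson response (log link) by maximum likelihood with the Laplace
#' approximation, where `night` enters as nights since the first control
#' (0, 1, 2). Reports Wald z tests for the trap-type and night effects and
#' the random-intercept s.d.
#'
#' @param records Trap-night data.frame with `line_id`, `trap_type`
#'   (`sbbt`/`bbbt`), `night` (1-3), `captures`, `accessible`.
#' @param alpha Significance level for the effect gates (default 0.05).
#' @return Object of class `capture_model`: list with the `fit`
#'   (`glmerMod`), `coef` table (estimate, se, z, p), `sigma_u`,
#'   `significant` (logical: any gated effect significant at `alpha`),
#'   and `alpha`.
#' @export
fit_capture_model <- function(records, alpha = 0.05) {
  if (length(unique(records$line_id)) < 2) stop("need >= 2 traplines")
  if (any(records$captures < 0) || any(records$captures %% 1 != 0)) {
    stop("captures must be non-negative integers")
  }
  if (all(records$captures == 0)) {
    stop("all-zero captures: no model can be fitted for this species")
  }
  d <- data.frame(
    captures = records$captures,
    bbbt = as.numeric(records$trap_type == "bbbt"),
    night0 = records$night - 1,
    line = factor(records$line_id),
    accessible = records$accessible
  )
  two_types <- length(unique(d$bbbt)) > 1
  form <- if (two_types) {
    captures ~ bbbt + night0 + (1 | line) + offset(log(accessible))
  } else {
    captures ~ night0 + (1 | line) + offset(log(accessible))
  }
  fit <- lme4::glmer(form, data = d, family = stats::poisson,
                     control = lme4::glmerControl(
                       optimizer = "bobyqa",
                       optCtrl = list(maxfun = 20000),
                       calc.derivs = FALSE))
  sm <- summary(fit)$coefficients
  coef_tab <- data.frame(term = rownames(sm), estimate = sm[, 1],
                         se = sm[, 2], z = sm[, 3], p = sm[, 4],
                         row.names = NULL)
  gated <- coef_tab[coef_tab$term %in% c("bbbt", "night0"), ]
  structure(list(fit = fit, coef = coef_tab,
                 sigma_u = sqrt(unlist(lme4::VarCorr(fit))[[1]]),
                 significant = any(gated$p < alpha), alpha = alpha,
                 data = d, records = records),
            class = "capture_model")
}

#' @export
print.capture_model <- function(x, ...) {
  cat("<capture_model> Poisson GLMM, log(accessible) offset\n")
  print(x$coef, digits = 3)
  cat(sprintf("sigma_u = %.3f; nuisance effect significant at %.2g: %s\n",
              x$sigma_u, x$alpha, x$significant))
  invisible(x)
}

#' Trapline abundance indices
#'
#' If the trap-type or night effect is significant (Wald test at the model's
#' `alpha`), the index for a trapline is the mean response-scale residual
#' (observed minus population-level fitted captures, random effect excluded)
#' over its trap-nights — removing the nuisance effects of trap kind and
#' control night while retaining line-level abundance signal. Otherwise the
#' index falls back to raw captures per 100 trap-nights over the line's
#' nominal effort (25 traps x nights). The path taken is recorded.
#'
#' @param model A `capture_model`, or (fallback-only) a raw trap-night
#'   data.frame.
#' @param species Species label.
#' @param residual_type `"response"` (default) or `"pearson"`.
#' @param traps_per_line Nominal traps per line for fallback effort
#'   (default 25).
#' @return data.frame of abundance observations (`unit`, `x`, `y`,
#'   `species`, `value`, `source = "trapline"`) with attribute
#'   `index_path` (`"residual"` or `"captures_per_100tn"`).
#' @export
abundance_indices <- function(model, species = "species",
                              residual_type = c("response", "pearson"),
                              traps_per_line = 25) {
  residual_type <- match.arg(residual_type)
  records <- if (inherits(model, "capture_model")) model$records else model
  use_residuals <- inherits(model, "capture_model") && model$significant
  per_line_xy <- unique(records[, c("line_id", "x", "y")])
  if (use_residuals) {
    mu <- stats::predict(model$fit, newdata = model$data, re.form = NA,
                         type = "response")
    res <- records$captures - mu
    if (residual_type == "pearson") res <- res / sqrt(mu)
    v <- tapply(res, records$line_id, mean)
    path <- "residual"
  } else {
    tot <- tapply(records$captures, records$line_id, sum)
    nights <- tapply(records$night, records$line_id,
                     function(n) length(unique(n)))
    v <- tot / (traps_per_line * nights) * 100
    path <- "captures_per_100tn"
  }
  out <- data.frame(unit = names(v),
                    x = per_line_xy$x[match(names(v), per_line_xy$line_id)],
                    y = per_line_xy$y[match(names(v), per_line_xy$line_id)],
                    species = species, value = as.numeric(v),
                    source = "trapline")
  attr(out, "index_path") <- path
  out
}
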