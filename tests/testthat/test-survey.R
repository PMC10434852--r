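test_that("transect scores count positive intervals and bound correctly", {
  rec <- expand.grid(interval = 1:20, transect_id = c("T1", "T2", "T3"))
  rec$x <- rec$interval * 8; rec$y <- 0
  rec$presence <- 0
  rec$presence[rec$transect_id == "T1"] <- 1                    # all positive
  rec$presence[rec$transect_id == "T2"] <- rep(c(1, 0), 10)      # alternating
  sc <- transect_scores(rec)
  expect_equal(sc$value[match(c("T1", "T2", "T3"), sc$unit)], c(20L, 10L, 0L))
  expect_equal(sc$x[sc$unit == "T1"], mean(1:20 * 8))
  expect_error(transect_scores(rec[-1, ]), "exactly 20")
})

test_that("capture model recovers effects and honours the offset identity", {
  sp <- species_effect_spec("x", terms = c(), baseline = log(0.05),
                            beta_type = 0.7, beta_night = -0.2,
                            trapline_sd = 0.3)
  tl <- generate_trapline_survey(fx_truth, fx_flat_abundance(0.05), 80, sp,
                                 seed = 41)
  m <- fit_capture_model(tl)
  est <- m$coef$estimate[m$coef$term == "bbbt"]
  expect_lt(abs(est - 0.7), 0.45) # single-draw sanity; sweep in acceptance
  # offset identity: doubling accessible doubles the fitted expectation
  nd <- m$data[1:2, ]
  nd$accessible <- c(10, 20)
  nd$bbbt <- 0; nd$night0 <- 0; nd$line <- m$data$line[1]
  mu <- stats::predict(m$fit, newdata = nd, type = "response")
  expect_equal(unname(mu[2] / mu[1]), 2, tolerance = 1e-8)
  expect_error(fit_capture_model(tl[tl$line_id == "L001", ]), ">= 2 traplines")
  tl0 <- tl; tl0$captures <- 0
  expect_error(fit_capture_model(tl0), "all-zero")
})

test_that("index falls back to captures per 100 trap-nights without effects", {
  # 2 lines, 25 traps x 3 nights, no nuisance effects in truth
  rec <- expand.grid(night = 1:3, line_id = c("A", "B"))
  rec$x <- 0; rec$y <- 0; rec$habitat <- "grassland"
  rec$trap_type <- "sbbt"; rec$accessible <- 25
  rec$captures <- c(2, 2, 2, 1, 1, 0) # A: 6 captures, B: 2
  idx <- abundance_indices(rec, species = "x")
  expect_equal(attr(idx, "index_path"), "captures_per_100tn")
  expect_equal(idx$value[idx$unit == "A"], 6 / 75 * 100)
  expect_equal(idx$value[idx$unit == "B"], 2 / 75 * 100)
})

test_that("significant nuisance effects switch the index to model residuals", {
  sp <- species_effect_spec("x", terms = c(), baseline = log(0.06),
                            beta_type = 1.2, beta_night = 0, trapline_sd = 0.2)
  tl <- generate_trapline_survey(fx_truth, fx_flat_abundance(0.06), 60, sp,
                                 seed = 43)
  m <- fit_capture_model(tl)
  expect_true(m$significant)
  idx <- abundance_indices(m, species = "x")
  expect_equal(attr(idx, "index_path"), "residual")
  # residuals average observed minus population-level fitted per line
  mu <- stats::predict(m$fit, newdata = m$data, re.form = NA, type = "response")
  byline <- tapply(tl$captures - mu, tl$line_id, mean)
  expect_equal(idx$value, as.numeric(byline[idx$unit]))
})

test_that("the trapline index tracks the latent abundance surface", {
  tl <- generate_trapline_survey(fx_truth, fx_abundance, 60, fx_species,
                                 seed = 45)
  m <- fit_capture_model(tl)
  idx <- abundance_indices(m, species = "vole")
  truth_by_line <- tapply(tl$true_abundance, tl$line_id, mean)
  rho <- cor(idx$value, truth_by_line[idx$unit], method = "spearman")
  expect_gte(rho, 0.7)
})
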