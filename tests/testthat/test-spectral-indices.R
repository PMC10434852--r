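# independent pixel-level re-evaluation of each index formula
oracle_index <- function(b, name) {
  with(b, switch(name,
    NDVI = (nir - red) / (nir + red),
    NDWI = (nir - swir1) / (nir + swir1),
    NDWI_MCF = (green - nir) / (green + nir),
    MNDWI = (green - swir1) / (green + swir1),
    EVI = 2.5 * (nir - red) / (nir + 6 * red - 7.5 * blue + 1),
    GRVI = (green - red) / (green + red),
    DVI = nir - red,
    TVI = 0.5 * (120 * (nir - green) - 200 * (red - green)),
    SVVI = apply(cbind(blue, green, red, nir, swir1, swir2), 1, sd) -
      apply(cbind(nir, swir1, swir2), 1, sd),
    SAVI = 1.5 * (nir - red) / (nir + red + 0.5)
  ))
}

test_that("every index matches hand evaluation on random reflectance", {
  sc <- random_scene(10, 10, seed = 42)
  b <- lapply(sc$bands, as.vector)
  for (nm in c("NDVI", "NDWI", "NDWI_MCF", "MNDWI", "EVI", "GRVI", "DVI",
               "TVI", "SVVI", "SAVI")) {
    got <- as.vector(compute_index(sc, nm)$values)
    expect_equal(got, oracle_index(b, nm), tolerance = 1e-10,
                 info = nm, ignore_attr = TRUE)
  }
})

test_that("worked examples evaluate to their hand-computed values", {
  mk <- function(blue = 0.05, green = 0.2, red = 0.1, nir = 0.5,
                 swir1 = 0.3, swir2 = 0.2) {
    eo_scene(lapply(list(blue = blue, green = green, red = red, nir = nir,
                         swir1 = swir1, swir2 = swir2),
                    function(v) matrix(v, 1, 1)),
             valid = matrix(TRUE, 1, 1), doy = 180)
  }
  sc <- mk()
  expect_equal(compute_index(sc, "NDVI")$values[1, 1], 0.4 / 0.6)
  expect_equal(compute_index(sc, "EVI")$values[1, 1],
               2.5 * 0.4 / (0.5 + 0.6 - 0.375 + 1))
  expect_equal(compute_index(sc, "SAVI")$values[1, 1], 1.5 * 0.4 / 1.1)
  # symmetry and zero-variance cases
  eq <- mk(nir = 0.1)
  expect_equal(compute_index(eq, "NDVI")$values[1, 1], 0)
  expect_equal(compute_index(eq, "DVI")$values[1, 1], 0)
  flat <- mk(blue = 0.3, green = 0.3, red = 0.3, nir = 0.3,
             swir1 = 0.3, swir2 = 0.3)
  expect_equal(compute_index(flat, "SVVI")$values[1, 1], 0)
})

test_that("normalized-difference outputs stay in [-1, 1] and masks propagate", {
  sc <- random_scene(15, 15, seed = 7)
  sc$valid[1:5, 1:5] <- FALSE
  for (nm in c("NDVI", "NDWI", "MNDWI", "GRVI", "DVI")) {
    ir <- compute_index(sc, nm)
    expect_true(all(abs(ir$values[ir$valid]) <= 1), info = nm)
    expect_true(all(is.na(ir$values[1:5, 1:5])), info = nm)
  }
  expect_error(compute_index(sc, "NOPE"), "unknown index")
})

test_that("pixelwise purity: permuting pixels permutes outputs identically", {
  sc <- random_scene(8, 8, seed = 3)
  perm <- sample(64)
  sc2 <- sc
  sc2$bands <- lapply(sc$bands, function(b) matrix(b[perm], 8, 8))
  for (nm in c("NDVI", "EVI", "SVVI")) {
    a <- as.vector(compute_index(sc, nm)$values)[perm]
    b <- as.vector(compute_index(sc2, nm)$values)
    expect_equal(a, b, info = nm)
  }
})

test_that("tasselled cap reproduces its published coefficients and is linear", {
  zero <- eo_scene(lapply(stats::setNames(nm = c("blue", "green", "red", "nir",
                                                 "swir1", "swir2")),
                          function(b) matrix(0, 2, 2)),
                   valid = matrix(TRUE, 2, 2), doy = 1, sensor = "TM")
  tc0 <- tasseled_cap(zero)
  expect_true(all(tc0$TCB$values == 0) && all(tc0$TCG$values == 0) &&
                all(tc0$TCW$values == 0))
  # unit reflectance on the first (blue) band returns the band-1 coefficients
  unit <- zero
  unit$bands$blue <- matrix(1, 2, 2)
  tc1 <- tasseled_cap(unit)
  expect_equal(tc1$TCB$values[1, 1], 0.2043)
  expect_equal(tc1$TCG$values[1, 1], -0.1603)
  expect_equal(tc1$TCW$values[1, 1], 0.0315)
  # homogeneity and additivity on random scenes, both sensors
  for (sensor in c("TM", "OLI")) {
    x <- random_scene(6, 6, seed = 11, sensor = sensor)
    y <- random_scene(6, 6, seed = 12, sensor = sensor)
    mix <- x
    mix$bands <- Map(function(a, b) 2 * a + 0.5 * b, x$bands, y$bands)
    tcm <- tasseled_cap(mix)
    tcx <- tasseled_cap(x); tcy <- tasseled_cap(y)
    for (cmp in c("TCB", "TCG", "TCW")) {
      expect_equal(tcm[[cmp]]$values,
                   2 * tcx[[cmp]]$values + 0.5 * tcy[[cmp]]$values,
                   tolerance = 1e-12, info = paste(sensor, cmp))
    }
  }
  bad <- zero; bad$sensor <- "MODIS"
  expect_error(tasseled_cap(bad), "unknown sensor")
})
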