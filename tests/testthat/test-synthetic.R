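small_cfg <- function(...) {
  virtual_species_config(nrow = 40, ncol = 40, n_presences = 60, ...)
}

test_that("landscape generation is seeded, sized and ordered correctly", {
  cfg <- small_cfg(seed = 5)
  a <- generate_landscape(cfg, "native")
  b <- generate_landscape(cfg, "native")
  expect_identical(a$monthly$tmean, b$monthly$tmean) # bit-identical rasters
  expect_identical(a$monthly$prec, b$monthly$prec)
  expect_equal(dim(a$monthly$tmean), c(40L, 40L, 12L))
  expect_true(all(a$monthly$tmin <= a$monthly$tmean + 1e-12))
  expect_true(all(a$monthly$tmean <= a$monthly$tmax + 1e-12))
  expect_true(all(a$monthly$prec >= 0))
  # a different tag yields a different landscape
  expect_false(identical(a$monthly$tmean,
                         generate_landscape(cfg, "invaded")$monthly$tmean))
  expect_error(virtual_species_config(nrow = 5, ncol = 40), "at least 10")
})

test_that("smoother settings increase spatial autocorrelation", {
  moran <- vapply(c(0.2, 0.6, 0.9), function(sm) {
    f <- nicheshift:::smooth_field(60, 60, sm, seed = 11)
    morans_i(f)
  }, numeric(1))
  expect_true(all(diff(moran) > 0))
})

test_that("true suitability peaks at the optimum and is symmetric", {
  cfg <- small_cfg(seed = 6)
  land <- generate_landscape(cfg, "native")
  pred <- climate_predictors(land$monthly)
  s <- true_suitability(pred, cfg$optimum, cfg$breadth, cfg$plateau)
  expect_true(all(s$values > 0 & s$values < 1))
  qf <- ((pred$bio1$values - cfg$optimum["bio1"]) / cfg$breadth["bio1"])^2 +
    ((pred$bio12$values - cfg$optimum["bio12"]) / cfg$breadth["bio12"])^2
  expect_equal(which.max(s$values), which.min(qf)) # peak nearest the optimum
  # symmetry in the scaled displacement
  stack2 <- pred
  stack2$bio1$values <- 2 * cfg$optimum["bio1"] - pred$bio1$values
  s2 <- true_suitability(stack2, cfg$optimum, cfg$breadth, cfg$plateau)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  # a very negative plateau kills suitability everywhere
  s3 <- true_suitability(pred, cfg$optimum, cfg$breadth, plateau = -50)
  expect_lt(max(s3$values), 1e-10)
  expect_error(true_suitability(pred, c(nope = 1), c(nope = 1)), "missing")
})

test_that("presence sampling follows the suitability surface", {
  set.seed(7)
  suit <- raster_grid(matrix(runif(100, 0.05, 1), 10, 10))
  occ <- sample_presences(suit, 40, seed = 8)
  expect_equal(nrow(occ$records), 40)
  expect_identical(occ$records, sample_presences(suit, 40, seed = 8)$records)
  # log-frequency against log-suitability has unit slope
  big <- sample_presences(suit, 20000, seed = 9)
  cells <- cell_from_xy(suit, big$records$longitude, big$records$latitude)
  freq <- tabulate(cells, nbins = 100)
  fit <- lm(log(freq + 0.5) ~ log(as.vector(suit$values)))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
  zero <- raster_grid(matrix(0, 5, 5))
  expect_error(sample_presences(zero, 5), "zero everywhere")
})

test_that("the invasion study wires the configured niche shift into truth", {
  cfg <- small_cfg(seed = 10, delta_sd = 2)
  st <- generate_invasion_study(cfg)
  tr <- st$truth
  expect_named(st$ranges, range_labels())
  # the invaded optimum equals the native optimum plus the recorded shift
  expect_equal(tr$optima$invasive_conus,
               tr$optima$native + tr$shift_vars$invasive_conus)
  expect_equal(sqrt(sum((tr$shift_vars$invasive_conus / tr$native_sd)^2)), 2)
  expect_equal(tr$delta_sd, 2)
  for (r in range_labels()) {
    rg <- st$ranges[[r]]
    expect_s3_class(rg$predictors, "raster_stack")
    expect_length(rg$predictors, 20L)
    expect_equal(nrow(rg$occurrences$records), cfg$n_presences)
    expect_true(all(rg$suitability$values > 0))
  }
  # derived predictors close the loop with the direct formulas
  dd <- degree_days(st$ranges$native$monthly)
  expect_equal(dd$values, st$ranges$native$predictors$degdays10$values)
  cell <- 17
  want <- oracle_bioclim_cell(st$ranges$native$monthly$tmin[1, cell, ],
                              st$ranges$native$monthly$tmax[1, cell, ],
                              st$ranges$native$monthly$tmean[1, cell, ],
                              st$ranges$native$monthly$prec[1, cell, ])
  got <- vapply(paste0("bio", 1:19), function(nm) {
    st$ranges$native$predictors[[nm]]$values[1, cell]
  }, numeric(1))
  expect_equal(unname(got), unname(want), tolerance = 1e-9)
})

test_that("sampling bias concentrates occurrences where the bias field is high", {
  cfg <- small_cfg(seed = 12, bias_strength = 3)
  st <- generate_invasion_study(cfg)
  rg <- st$ranges$native
  expect_false(is.null(rg$bias))
  cells <- cell_from_xy(rg$bias, rg$occurrences$records$longitude,
                        rg$occurrences$records$latitude)
  # mean bias at sampled cells exceeds the landscape average
  expect_gt(mean(rg$bias$values[cells]), mean(rg$bias$values))
})
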