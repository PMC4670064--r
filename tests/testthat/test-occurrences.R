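write_occ_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("occurrence CSV parsing keeps valid rows and reports bad ones", {
  df <- make_occ_df(c(-55, -54.5, -56), c(-25, -24, -23))
  occ <- read_occurrences(write_occ_csv(df))
  expect_equal(nrow(occ$records), 3)
  # out-of-range longitude is rejected and reported by row
  df_bad <- df
  df_bad$longitude[2] <- 200
  occ2 <- read_occurrences(write_occ_csv(df_bad))
  expect_equal(nrow(occ2$records), 2)
  expect_equal(attr(occ2, "rejected"), 2L)
  expect_equal(occ2$log$n_removed, 1L)
  # unknown range label rejected
  df_bad2 <- df
  df_bad2$range_label[1] <- "alien"
  expect_equal(nrow(read_occurrences(write_occ_csv(df_bad2))$records), 2)
  # empty file warns, missing column is a hard error
  expect_warning(empty <- read_occurrences(write_occ_csv(df[0, ])), "empty")
  expect_equal(nrow(empty$records), 0)
  expect_error(read_occurrences(write_occ_csv(df[, -2])), "longitude")
})

test_that("grid deduplication keeps the first record per cell and logs counts", {
  g <- raster_grid(matrix(0, 10, 10), xmin = -56, ymin = -26, cellsize = 0.1)
  occ <- occurrence_set(make_occ_df(c(-55.55, -55.58, -55.2),
                                    c(-25.55, -25.52, -25.2)))
  out <- dedupe_to_grid(occ, g)
  expect_equal(out$records$id, c("r001", "r003"))
  expect_equal(out$log$n_in, 3L)
  expect_equal(out$log$n_kept + out$log$n_removed, out$log$n_in)
  # records in distinct cells are untouched
  occ2 <- occurrence_set(make_occ_df(c(-55.55, -55.2), c(-25.55, -25.2)))
  expect_equal(nrow(dedupe_to_grid(occ2, g)$records), 2)
})

test_that("spatial thinning enforces the minimum distance", {
  # two points about 3 km apart: exactly one survives a 10 km rule
  occ <- occurrence_set(make_occ_df(c(-55, -55.03), c(-25, -25)))
  expect_equal(nrow(spatial_thin(occ, 10, seed = 1)$records), 1)
  # all pairs beyond the rule: unchanged
  occ2 <- occurrence_set(make_occ_df(c(-55, -54, -53), c(-25, -25, -25)))
  expect_equal(nrow(spatial_thin(occ2, 10, seed = 1)$records), 3)
})

test_that("thinning is seed-reproducible and verified by brute force", {
  set.seed(33)
  for (rep in 1:3) {
    occ <- occurrence_set(make_occ_df(runif(60, -56, -55), runif(60, -26, -25)))
    a <- spatial_thin(occ, 8, seed = 99)
    b <- spatial_thin(occ, 8, seed = 99)
    expect_identical(a$records, b$records)
    # brute-force pairwise check of the retained set
    p <- project_cea(a$records$longitude, a$records$latitude)
    d <- as.matrix(dist(p)) / 1000
    diag(d) <- Inf
    expect_gte(min(d), 8)
    expect_equal(a$log$n_kept[nrow(a$log)], nrow(a$records))
  }
})

test_that("bias surface peaks at the data and flattens with bandwidth", {
  g <- raster_grid(matrix(0, 20, 20), xmin = -56, ymin = -26, cellsize = 0.05)
  one <- occurrence_set(make_occ_df(-55.525, -25.525))
  bs <- bias_surface(one, g, bandwidth_km = 10)
  expect_equal(unname(which.max(bs$values)),
               unname(cell_from_xy(g, -55.525, -25.525)))
  expect_equal(max(bs$values), 1)
  expect_gte(min(bs$values), 1e-6)
  # enormous bandwidth approaches a uniform surface
  flat <- bias_surface(one, g, bandwidth_km = 1e6)
  expect_lt(stats::sd(flat$values) / mean(flat$values), 1e-4)
  # no records: uniform with a warning
  none <- occurrence_set(make_occ_df(numeric(0), numeric(0)))
  expect_warning(u <- bias_surface(none, g, 10), "uniform")
  expect_true(all(u$values == 1))
})

test_that("background sampling follows the bias weights", {
  mask <- raster_grid(matrix(1, 40, 40))
  # uniform sampling: chi-square goodness of fit over halves is unsuspicious
  bg <- sample_background(mask, n = 1200, seed = 5)
  expect_equal(nrow(bg$points), 1200)
  expect_identical(bg$points,
                   sample_background(mask, n = 1200, seed = 5)$points)
  left <- sum(bg$points$x < 20)
  expect_gt(stats::chisq.test(c(left, 1200 - left))$p.value, 0.01)
  # bias concentrated on one half: sampled fraction tracks the weight ratio
  big <- raster_grid(matrix(1, 300, 300))
  bias <- big
  bias$values[] <- ifelse(xy_from_cell(big)$x < 150, 1, 1 / 3)
  bg2 <- sample_background(big, n = 3000, bias = bias, seed = 6)
  frac_left <- mean(bg2$points$x < 150)
  expect_lt(abs(frac_left - 0.75), 0.02)
  # n beyond the available cells returns all cells with a warning
  small <- raster_grid(matrix(1, 3, 3))
  expect_warning(all_cells <- sample_background(small, n = 50), "using all")
  expect_equal(nrow(all_cells$points), 9)
  empty <- raster_grid(matrix(NA_real_, 3, 3))
  expect_error(sample_background(empty, 5), "empty")
})
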