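test_that("land-use binarization maps residential classes to 1", {
  lu <- toy_landuse_3x3()
  b <- binarize_landuse(lu)
  expect_equal(sum(b$values), 4)          # 4 of 9 cells are residential
  all_res <- raster_layer(matrix(1, 3, 3), resolution_m = 10,
                          levels = lu$levels)
  expect_true(all(binarize_landuse(all_res)$values == 1))
  none <- raster_layer(matrix(6, 3, 3), resolution_m = 10,
                       levels = lu$levels)
  expect_true(all(binarize_landuse(none)$values == 0))
  expect_warning(binarize_landuse(lu, c("private residential", "castle")),
                 "castle")
  expect_error(binarize_landuse(lu, character(0)), "non-empty")
})

test_that("buffer features have the right closed forms on uniform cities", {
  n <- 60
  lv <- toy_landuse_3x3()$levels
  all_res <- raster_layer(matrix(1, n, n), resolution_m = 10, levels = lv)
  res <- binarize_landuse(all_res)
  veg <- raster_layer(matrix(0, n, n), resolution_m = 10)
  h <- raster_layer(matrix(17.5, n, n), resolution_m = 10)
  f <- buffer_features(300, 300, res, veg, h, radius_m = 150)
  expect_equal(f$pct_residential, 100)
  expect_equal(f$pct_vegetation, 0)
  expect_equal(f$avg_build_height_m, 17.5)  # constant height: avg = h
  expect_equal(f$std_build_height_m, 0)     # ... and zero spread
  expect_false(f$no_buildings)
  # no built cells: avg = std = 0 with the flag set
  h0 <- raster_layer(matrix(0, n, n), resolution_m = 10)
  f0 <- buffer_features(300, 300, res, veg, h0, radius_m = 150)
  expect_true(f0$no_buildings)
  expect_equal(f0$avg_build_height_m, 0)
  expect_error(buffer_features(-5, 300, res, veg, h, ids = "p1"), "p1")
})

test_that("half-plane residential split gives ~50% at 1-m resolution", {
  n <- 900
  m <- matrix(0, n, n)
  m[, 1:450] <- 1   # residential iff x < 450
  res <- raster_layer(m, resolution_m = 1)
  veg <- raster_layer(matrix(0, n, n), resolution_m = 1)
  h <- raster_layer(matrix(10, n, n), resolution_m = 1)
  f <- buffer_features(450, 450, res, veg, h, radius_m = 400)
  expect_lt(abs(f$pct_residential - 50), 1)
  o <- bf_buffer_oracle(450, 450, res, veg, h, 400)
  expect_equal(f$pct_residential, o$pct_residential, tolerance = 1e-12)
})

test_that("buffer features match the brute-force cell-enumeration oracle", {
  cfg <- small_city(seed = 5)
  r <- generate_rasters(cfg)
  res <- binarize_landuse(r$land_use)
  set.seed(11)
  x <- runif(20, 300, 1200)
  y <- runif(20, 300, 1200)
  f <- buffer_features(x, y, res, r$vegetation, r$building_height,
                       radius_m = 400)
  for (k in 1:20) {
    o <- bf_buffer_oracle(x[k], y[k], res, r$vegetation, r$building_height,
                          400)
    expect_equal(f$pct_residential[k], o$pct_residential, tolerance = 1e-12)
    expect_equal(f$pct_vegetation[k], o$pct_vegetation, tolerance = 1e-12)
    expect_equal(f$avg_build_height_m[k], o$avg, tolerance = 1e-12)
    expect_equal(f$std_build_height_m[k], o$std, tolerance = 1e-12)
  }
  # complement identity on fully valid buffers
  nonres <- raster_layer(1 - res$values, resolution_m = res$resolution_m)
  fn <- buffer_features(x, y, nonres, r$vegetation, r$building_height,
                        radius_m = 400)
  expect_equal(f$pct_residential + fn$pct_residential, rep(100, 20))
})

test_that("buffer features are stable under resolution refinement", {
  cfg <- city_config(extent_m = 800, base_resolution_m = 10, n_tpu = 4,
                     n_subjects = 10, seed = 9)
  r <- generate_rasters(cfg)
  res10 <- binarize_landuse(r$land_use)
  res2 <- resample_raster(res10, 2)
  veg2 <- resample_raster(r$vegetation, 2)
  h2 <- resample_raster(r$building_height, 2)
  pts <- data.frame(x = c(350, 400, 480), y = c(420, 390, 350))
  f10 <- buffer_features(pts$x, pts$y, res10, r$vegetation,
                         r$building_height, radius_m = 300)
  f2 <- buffer_features(pts$x, pts$y, res2, veg2, h2, radius_m = 300)
  expect_equal(f10$pct_residential, f2$pct_residential, tolerance = 0.01)
  expect_equal(f10$pct_vegetation, f2$pct_vegetation, tolerance = 0.01)
  expect_equal(f10$avg_build_height_m, f2$avg_build_height_m,
               tolerance = 0.01)
  expect_equal(f10$std_build_height_m, f2$std_build_height_m,
               tolerance = 0.01)
})

test_that("percentile normalization follows the Hazen plotting position", {
  expect_equal(percentile_normalize(c(7, 7, 7)), rep(50, 3))
  expect_equal(percentile_normalize(c(10, 20, 30, 40)),
               c(12.5, 37.5, 62.5, 87.5))
  set.seed(4)
  v <- c(rnorm(40), sample(rnorm(5), 10, replace = TRUE))  # with ties
  expect_equal(percentile_normalize(v), bf_percentile_oracle(v))
  # order-preserving and invariant to strictly monotone transforms
  expect_equal(percentile_normalize(v), percentile_normalize(exp(v)))
  expect_equal(order(percentile_normalize(v)), order(v))
  expect_error(percentile_normalize(rep(NA_real_, 3)), "finite")
})
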