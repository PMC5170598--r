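test_that("write/read round-trip preserves values and grid metadata", {
  g <- grid_spec(4, 4, pixel_size = 250, origin_x = 1000, origin_y = 9000,
                 crs_id = "utm-43n")
  # integer map: exact round-trip
  codes <- matrix(c(1:7, NA, 9:16), 4, 4)
  cm <- categorical_map(g, codes, legend = NULL)
  f <- withr::local_tempfile(fileext = ".tif")
  write_raster(cm, f)
  back <- read_raster(f)
  expect_s3_class(back, "categorical_map")
  expect_identical(back$codes, cm$codes)
  expect_true(same_grid(back$grid, g))
  expect_identical(back$grid$crs_id, "utm-43n")

  # float map: round-trip within 1e-6 for NDVI-range data
  vals <- matrix(seq(-0.9, 0.9, length.out = 16), 4, 4)
  vals[2, 3] <- NA
  sm <- scalar_map(g, vals, units = "ndvi")
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_raster(sm, f2)
  back2 <- read_raster(f2)
  expect_equal(back2$values, sm$values, tolerance = 1e-6)
  expect_identical(is.na(back2$values), is.na(sm$values))
  expect_identical(back2$units, "ndvi")
})

test_that("irrigation maps are written as single-band 0/1 integer rasters", {
  g <- fixture_grid()
  lab <- matrix(0L, 4, 4)
  im0 <- irrigation_map(g, lab, "2000-01")
  f <- withr::local_tempfile(fileext = ".tif")
  write_raster(im0, f)
  back <- read_raster(f)
  expect_identical(unique(as.vector(back$labels)), 0L)

  lab[1, ] <- 1L
  lab[4, 4] <- NA                     # outside the analysis extent
  im <- irrigation_map(g, lab, "2000-01")
  write_raster(im, f)
  back <- read_raster(f)
  expect_identical(back$labels, im$labels)
  expect_identical(back$water_year, "2000-01")
  sidecar <- jsonlite::read_json(paste0(f, ".aux.json"))
  expect_equal(sidecar$grid$nodata, -9999)
  expect_identical(sidecar$kind, "irrigation_map")
})

test_that("multi-band stacks round-trip with dates and support band selection", {
  g <- fixture_grid()
  dates <- seq(as.Date("2000-06-05"), by = 16, length.out = 23)
  vals <- array(runif(4 * 4 * 23, -0.2, 0.9), c(4, 4, 23))
  st <- ndvi_stack(g, vals, dates, "2000-01")
  f <- withr::local_tempfile(fileext = ".tif")
  write_raster(st, f)
  back <- read_raster(f)
  expect_s3_class(back, "ndvi_stack")
  expect_identical(dim(back$values)[3], 23L)
  expect_equal(back$values, st$values, tolerance = 1e-6)
  expect_identical(back$dates, dates)

  sub <- read_raster(f, band_selection = c(1, 5, 23))
  expect_identical(dim(sub$values)[3], 3L)
  expect_identical(sub$dates, dates[c(1, 5, 23)])
})

test_that("integer-scaled NDVI encoding converts by the declared 1e-4 factor", {
  g <- fixture_grid()
  dates <- as.Date("2000-06-05")
  vals <- array(0.15, c(4, 4, 1))
  vals[1, 1, 1] <- 0.8               # stored as the integer 8000
  st <- ndvi_stack(g, vals, dates, "2000-01")
  f <- withr::local_tempfile(fileext = ".tif")
  write_raster(st, f, encoding = "int16")
  sidecar <- jsonlite::read_json(paste0(f, ".aux.json"))
  expect_equal(sidecar$encoding$scale_factor, 1e-4)
  back <- read_raster(f)
  expect_identical(back$values[1, 1, 1], 0.8)
  expect_identical(back$values[2, 2, 1], 0.15)
})

test_that("a bare TIFF without sidecar reads with a warning and no nodata", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 2, 2), f)
  expect_warning(out <- read_raster(f), "no sidecar")
  expect_s3_class(out, "scalar_map")
  expect_false(anyNA(out$values))
})

test_that("read_raster rejects missing files", {
  expect_error(read_raster(file.path(tempdir(), "absent.tif")), "not found")
})

test_that("build_ndvic keeps exactly the water-year composites, sorted", {
  g <- fixture_grid()
  dates <- seq(as.Date("2000-01-01"), by = 16, length.out = 46)
  comps <- lapply(seq_along(dates), function(i) matrix(i / 100, 4, 4))
  st <- build_ndvic(comps, dates, "2000-01", grid = g)
  expect_identical(dim(st$values)[3], 23L)
  expect_true(min(st$dates) >= as.Date("2000-06-01"))
  expect_true(max(st$dates) <= as.Date("2001-05-31"))
  expect_true(all(diff(as.numeric(st$dates)) > 0))

  # permutation invariance
  perm <- sample(length(dates))
  st2 <- build_ndvic(comps[perm], dates[perm], "2000-01", grid = g)
  expect_identical(st2$values, st$values)
  expect_identical(st2$dates, st$dates)

  expect_error(build_ndvic(comps[1:3], dates[1:3], "2050-51", grid = g),
               "no composites")
  expect_error(build_ndvic(comps[c(20, 20)], dates[c(20, 20)], "2000-01",
                           grid = g), "duplicate")
  comps_bad <- comps
  comps_bad[[20]] <- matrix(0, 3, 3)
  expect_error(build_ndvic(comps_bad, dates, "2000-01", grid = g), "differ")
})

test_that("align_to_grid aggregates by majority / area-weighted mean", {
  src_g <- grid_spec(4, 4, pixel_size = 125, origin_x = 0, origin_y = 500)
  tgt_g <- grid_spec(2, 2, pixel_size = 250, origin_x = 0, origin_y = 500)
  codes <- matrix(c(1L, 1L, 2L, 3L,
                    1L, 1L, 3L, 3L,
                    4L, 4L, 5L, 5L,
                    4L, 4L, 5L, 5L), 4, 4, byrow = TRUE)
  cm <- categorical_map(src_g, codes)
  out <- align_to_grid(cm, tgt_g, rule = "majority")
  expect_identical(out$codes[1, 1], 1L)   # {1,1,1,1}
  expect_identical(out$codes[1, 2], 3L)   # {2,3,3,3}
  expect_identical(out$codes[2, 2], 5L)

  # every 2x2 source block is {10, 30, 10, 30} -> area-weighted mean 20
  slope <- scalar_map(src_g, matrix(c(10, 30), 4, 4), units = "percent")
  outm <- align_to_grid(slope, tgt_g, rule = "mean")
  expect_equal(outm$values, matrix(20, 2, 2))

  # 2x2 block {1,1,2,3} -> majority 1; tie {1,1,2,2} -> lowest code
  tie <- categorical_map(grid_spec(2, 2, pixel_size = 125),
                         matrix(c(1L, 2L, 1L, 2L), 2, 2))
  one <- align_to_grid(tie, grid_spec(1, 1, pixel_size = 250,
                                      origin_y = 250), "majority")
  expect_identical(one$codes[1, 1], 1L)
})

test_that("align_to_grid is the identity on matching grids and refuses CRS mixes", {
  g <- fixture_grid()
  sm <- scalar_map(g, matrix(runif(16), 4, 4))
  expect_identical(align_to_grid(sm, g, "mean"), sm)
  g2 <- grid_spec(4, 4, crs_id = "different")
  expect_error(align_to_grid(sm, g2, "mean"), "CRS mismatch")
  far <- grid_spec(2, 2, pixel_size = 250, origin_x = 1e6, origin_y = 1e6)
  expect_error(align_to_grid(sm, far, "mean"), "overlap")
})

test_that("ndvi_stack validates range, dates and water-year window", {
  g <- fixture_grid()
  d <- seq(as.Date("2000-06-05"), by = 16, length.out = 3)
  expect_error(ndvi_stack(g, array(1.5, c(4, 4, 3)), d, "2000-01"),
               "\\[-1, 1\\]")
  expect_error(ndvi_stack(g, array(0.1, c(4, 4, 3)), rev(d), "2000-01"),
               "increasing")
  expect_error(ndvi_stack(g, array(0.1, c(4, 4, 3)), d, "2003-04"),
               "outside water year")
})
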