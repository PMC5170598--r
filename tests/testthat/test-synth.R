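test_that("scenes are seeded-deterministic and respect physical bounds", {
  cfg <- scene_config(n_rows = 24, n_cols = 24, seed = 123)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$ndvi$values, b$ndvi$values)
  expect_identical(a$truth, b$truth)
  expect_identical(a$red, b$red)

  expect_true(all(a$ndvi$values >= -1 & a$ndvi$values <= 1))
  expect_true(all(a$red >= 0 & a$red <= 1))
  expect_true(all(a$nir >= 0 & a$nir <= 1))
  expect_identical(dim(a$ndvi$values)[3], 23L)

  # different seed, different scene
  c2 <- generate_scene(scene_config(n_rows = 24, n_cols = 24, seed = 124))
  expect_false(identical(a$ndvi$values, c2$ndvi$values))
})

test_that("emitted reflectance is consistent with emitted NDVI", {
  b <- generate_scene(scene_config(n_rows = 16, n_cols = 16, seed = 3))
  ndvi_back <- (b$nir - b$red) / (b$nir + b$red)
  expect_equal(ndvi_back, b$ndvi$values, tolerance = 1e-6)
})

test_that("the irrigated boost is exact when noise is off", {
  cfg <- scene_config(n_rows = 32, n_cols = 32, seed = 9, noise_sd = 0)
  b <- generate_scene(cfg)
  tr <- b$truth
  peaks <- apply(cbind(tr$row, tr$col), 1L, function(p)
    max(b$ndvi$values[p[1], p[2], ]))
  for (crop in names(cfg$crops)) {
    irr <- peaks[tr$sown & tr$crop == crop & tr$irrigated]
    rf <- peaks[tr$sown & tr$crop == crop & !tr$irrigated]
    expect_equal(min(irr) - max(rf), 0.2, tolerance = 1e-9)
    expect_equal(max(irr) - min(irr), 0, tolerance = 1e-9)
  }
})

test_that("truth labels line up with the raster layers", {
  b <- generate_scene(scene_config(n_rows = 16, n_cols = 16, seed = 21))
  tr <- b$truth
  expect_identical(b$lulc$codes[cbind(tr$row, tr$col)], tr$lulc)
  steep_slopes <- b$slope$values[cbind(tr$row, tr$col)][tr$steep]
  expect_true(all(steep_slopes > 20))
  expect_true(all(!tr$irrigated[tr$steep]))
  expect_true(all(!tr$irrigated[is.na(tr$crop)]))
})

test_that("drought scenarios scale rainfed peaks and keep pixel identities", {
  cfg <- scene_config(n_rows = 32, n_cols = 32, seed = 6, noise_sd = 0)
  base <- generate_scene(cfg)
  same <- scenario_drought(cfg, deficit = 0)
  expect_identical(same$ndvi$values, base$ndvi$values)

  dr <- scenario_drought(cfg, deficit = 0.3)
  tr <- base$truth
  sel <- tr$sown & !tr$irrigated
  p_base <- apply(cbind(tr$row, tr$col)[sel, ], 1L, function(p)
    max(base$ndvi$values[p[1], p[2], ]))
  p_dr <- apply(cbind(tr$row, tr$col)[sel, ], 1L, function(p)
    max(dr$ndvi$values[p[1], p[2], ]))
  # rainfed peaks reduced (exact 70% factor checked below with zero background)
  expect_true(all(p_dr < p_base))
  # irrigated peaks unchanged
  sel_i <- tr$sown & tr$irrigated
  p_base_i <- apply(cbind(tr$row, tr$col)[sel_i, ], 1L, function(p)
    max(base$ndvi$values[p[1], p[2], ]))
  p_dr_i <- apply(cbind(tr$row, tr$col)[sel_i, ], 1L, function(p)
    max(dr$ndvi$values[p[1], p[2], ]))
  expect_equal(p_dr_i, p_base_i)

  # reduced sown fraction turns some irrigated pixels fallow
  dr2 <- scenario_drought(cfg, deficit = 0.3, sown_reduction = 0.4)
  expect_lt(sum(dr2$truth$irrigated), sum(base$truth$irrigated))
  expect_true(all(dr2$truth$irrigated <= base$truth$irrigated))
})

test_that("scene bundles write to the formats the pipeline consumes", {
  b <- generate_scene(scene_config(n_rows = 8, n_cols = 8, seed = 2))
  dir <- withr::local_tempdir()
  write_scene(b, dir)
  expect_true(all(file.exists(file.path(
    dir, c("ndvi.tif", "lulc.tif", "slope.tif", "zones.tif",
           "zones.geojson", "truth.csv", "lookup.csv")))))
  nd <- read_raster(file.path(dir, "ndvi.tif"))
  expect_equal(nd$values, b$ndvi$values, tolerance = 1e-6)
  zones <- read_zones_geojson(file.path(dir, "zones.geojson"))
  zm <- zones_to_map(zones, b$ndvi$grid)
  expect_true(all(zm$codes == 1L))

  expect_error(scene_config(irrigated_boost = 0.5), "0.95")
})

test_that("the drought rainfed peak check uses the exact deficit factor", {
  cfg <- scene_config(n_rows = 24, n_cols = 24, seed = 6, noise_sd = 0,
                      base_ndvi = 0)
  base <- generate_scene(cfg)
  dr <- scenario_drought(cfg, deficit = 0.3)
  tr <- base$truth
  sel <- tr$sown & !tr$irrigated
  px <- cbind(tr$row, tr$col)[sel, ]
  p_base <- apply(px, 1L, function(p) max(base$ndvi$values[p[1], p[2], ]))
  p_dr <- apply(px, 1L, function(p) max(dr$ndvi$values[p[1], p[2], ]))
  expect_equal(p_dr / p_base, rep(0.7, sum(sel)), tolerance = 1e-9)
})
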