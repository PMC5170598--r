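test_that("height scaling maps the croppable NDVI range onto 1..100", {
  expect_equal(scale_height(0.1), 1)
  expect_equal(scale_height(0.8), 100)
  expect_equal(scale_height(0.45), 50.5)
  expect_equal(scale_height(0.05), 1)      # clamped below
  expect_equal(scale_height(0.95), 100)    # clamped above
  v <- seq(-0.2, 1, by = 0.01)
  expect_true(all(diff(scale_height(v)) >= 0))   # non-decreasing
  expect_error(scale_height(NaN), "finite")
})

test_that("cumulative departure finds the hand-worked emergence/senescence", {
  es <- cumulative_departure_dates(c(0, 0, 1, 1, 0, 0))
  expect_equal(es, c(emergence = 1, senescence = 3))

  # invariant to adding a constant (departures remove the mean)
  es2 <- cumulative_departure_dates(c(0, 0, 1, 1, 0, 0) + 0.37)
  expect_equal(es2, es)

  # constant profile carries no seasonal signal
  expect_null(cumulative_departure_dates(rep(0.3, 8)))
  expect_error(cumulative_departure_dates(c(1, 2)), "at least 3")
})

test_that("cumulative departure recovers generated season bounds within one composite", {
  for (on in c(1L, 3L, 6L)) {
    for (off in c(on + 5L, on + 8L)) {
      prof <- hump_profile(23L, on = on, off = off)
      es <- cumulative_departure_dates(prof)
      expect_lte(abs(es[["emergence"]] - on), 1)
      expect_lte(abs(es[["senescence"]] - off), 1)
    }
  }
})

test_that("NA gaps are interpolated before phenology", {
  prof <- hump_profile(23L, on = 3L, off = 10L)
  gappy <- prof
  gappy[c(6, 7)] <- NA
  es_full <- cumulative_departure_dates(prof)
  es_gap <- cumulative_departure_dates(gappy)
  expect_lte(abs(es_gap[["emergence"]] - es_full[["emergence"]]), 1)
  expect_lte(abs(es_gap[["senescence"]] - es_full[["senescence"]]), 1)
})

test_that("training lattice is a deterministic grid intersected with the mask", {
  g <- grid_spec(64, 64)
  full <- structure(list(grid = g, include = matrix(TRUE, 64, 64)),
                    class = "mask_layer")
  px <- select_training_pixels(full)
  expect_identical(nrow(px), 16L)                       # 4 x 4 lattice
  expect_identical(px, select_training_pixels(full))    # deterministic

  # spacing equal to the pixel size selects every masked pixel
  some <- full
  some$include[1:32, ] <- FALSE
  px2 <- select_training_pixels(some, spacing_m = 250)
  expect_identical(nrow(px2), sum(some$include))

  empty <- full
  empty$include[] <- FALSE
  expect_error(select_training_pixels(empty), "empty")
  expect_error(select_training_pixels(full, spacing_m = 100), "at least")
})

test_that("season descriptors are emitted per pool with the pool peak", {
  # single Kharif-window hump: FS descriptor plus a CMS descriptor, same peak
  prof <- hump_profile(23L, on = 2L, off = 9L, peak = 0.62)
  des <- extract_season_descriptors(prof)
  expect_setequal(des$pool, c("FS", "CMS"))
  fs <- des[des$pool == "FS", ]
  cms <- des[des$pool == "CMS", ]
  expect_equal(fs$peak_ndvi, cms$peak_ndvi)
  expect_equal(fs$peak_ndvi, max(prof))
  expect_identical(fs$season, "Kharif")
  expect_true(fs$emergence_idx < fs$senescence_idx)

  # double-cropped profile: FS and SS descriptors with distinct peaks
  prof2 <- pmax(hump_profile(23L, 1L, 7L, peak = 0.55),
                hump_profile(23L, 12L, 18L, peak = 0.75))
  des2 <- extract_season_descriptors(prof2)
  expect_true(all(c("FS", "SS") %in% des2$pool))
  expect_equal(des2$peak_ndvi[des2$pool == "FS"], 0.55, tolerance = 1e-6)
  expect_equal(des2$peak_ndvi[des2$pool == "SS"], 0.75, tolerance = 1e-6)
  expect_identical(des2$season[des2$pool == "SS"], "Rabi")

  # flat profile yields nothing
  expect_identical(nrow(extract_season_descriptors(rep(0.2, 23))), 0L)
})

test_that("crop assignment follows lookup priority and intervals", {
  lut <- fixture_lookup()
  des <- data.frame(pool = "FS", season = "Kharif", emergence_idx = 2,
                    senescence_idx = 10, duration = 8, peak_ndvi = 0.52,
                    height = 60, stringsAsFactors = FALSE)
  expect_identical(assign_crop_type(des, lut, 1L), "Rice")

  # height outside every interval -> unassigned
  des$height <- 20
  des$season <- "Rabi"
  expect_true(is.na(assign_crop_type(des, lut, 1L)))

  # two overlapping candidates: the higher-priority entry wins, repeatably
  lut2 <- rbind(lut, data.frame(zone_id = 1L, crop_name = "Maize",
                                season = "Kharif", height_min = 55,
                                height_max = 100, duration_min = 3,
                                duration_max = 12, priority = 0L))
  des$season <- "Kharif"
  des$height <- 60
  expect_identical(assign_crop_type(des, lut2, 1L), "Maize")
  expect_identical(assign_crop_type(des, lut2, 1L),
                   assign_crop_type(des, lut2, 1L))

  expect_error(assign_crop_type(des, lut, zone_id = 9L), "no entries")
  expect_true(is.na(assign_crop_type(des[0, ], lut, 1L)))
})

test_that("training samples are labelled from profiles and long gaps disqualify", {
  g <- grid_spec(2, 2)
  prof <- hump_profile(23L, on = 2L, off = 9L, peak = 0.6)   # Rice-like
  vals <- array(rep(prof, each = 4), c(2, 2, 23))
  vals[2, 2, 3:8] <- NA                                      # 6-composite gap
  st <- ndvi_stack(g, vals, seq(as.Date("2000-06-05"), by = 16,
                                length.out = 23), "2000-01")
  px <- cbind(row = c(1L, 1L, 2L, 2L), col = c(1L, 2L, 1L, 2L))
  tr <- build_training_samples(st, px, fixture_lookup(), 1L)
  expect_identical(nrow(tr$samples), 3L)       # gap pixel disqualified
  expect_true(all(tr$samples$crop == "Rice"))
  expect_identical(dim(tr$profiles), c(3L, 23L))
})
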