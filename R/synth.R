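#' Configuration of a synthetic agricultural scene
#'
#' Defines a co-registered bundle of NDVI/RED/NIR stacks, LULC, slope and
#' zone layers with known crop and irrigation labels, emulating the
#' statistical structure the classifier assumes: per-pixel seasonal NDVI
#' curves with crop-specific timing, an irrigated-vs-rainfed peak-NDVI gap,
#' and additive composite noise.  Defaults follow the study conditions: a
#' 250 m grid, a 23-composite water year, an irrigated peak boost of 0.2
#' NDVI over a rainfed peak of 0.6, composite noise sd 0.02, and roughly
#' half of the cropland irrigated.
#'
#' @param n_rows,n_cols grid size (default 64 x 64).
#' @param pixel_size pixel size in map units (default 250).
#' @param n_composites composites per water year (default 23).
#' @param seed integer seed; the same configuration always generates the
#'   same scene.
#' @param crops named list; each entry
#'   `list(season, sowing, duration, rainfed_peak)` with `sowing` the 0-based
#'   composite of green-up and `duration` in composites.
#' @param frac_irrigated fraction of cropped pixels irrigated (default 0.5).
#' @param frac_nonagricultural fraction of pixels that are not cropland
#'   (default 0.2).
#' @param frac_steep fraction of pixels on steep (>20%) terrain
#'   (default 0.05).
#' @param irrigated_boost peak-NDVI gap between irrigated and rainfed pixels
#'   of the same crop (default 0.2).
#' @param base_ndvi off-season background NDVI (default 0.15).
#' @param noise_sd additive Gaussian composite noise (default 0.02).
#' @param drought_deficit fraction by which rainfed peaks are reduced
#'   (default 0; see [scenario_drought()]).
#' @param sown_reduction fraction of irrigated pixels left unsown
#'   (default 0; see [scenario_drought()]).
#' @param water_year water-year label (default `"2000-01"`).
#' @param crs_id CRS identifier shared by all layers.
#' @return validated list of class `scene_config`.
#' @export
scene_config <- function(n_rows = 64L, n_cols = 64L, pixel_size = 250,
                         n_composites = 23L, seed = 1L,
                         crops = list(
                           Rice = list(season = "Kharif", sowing = 1L,
                                       duration = 8L, rainfed_peak = 0.6),
                           Wheat = list(season = "Rabi", sowing = 11L,
                                        duration = 7L, rainfed_peak = 0.6)),
                         frac_irrigated = 0.5,
                         frac_nonagricultural = 0.2,
                         frac_steep = 0.05,
                         irrigated_boost = 0.2,
                         base_ndvi = 0.15,
                         noise_sd = 0.02,
                         drought_deficit = 0,
                         sown_reduction = 0,
                         water_year = "2000-01",
                         crs_id = "local-meters") {
  stopifnot(n_rows > 0, n_cols > 0, n_composites >= 3,
            length(crops) >= 1L, !is.null(names(crops)),
            frac_irrigated >= 0, frac_irrigated <= 1,
            frac_nonagricultural >= 0, frac_nonagricultural <= 1,
            frac_steep >= 0, frac_steep <= 1,
            irrigated_boost >= 0, noise_sd >= 0,
            drought_deficit >= 0, drought_deficit <= 1,
            sown_reduction >= 0, sown_reduction <= 1)
  if (any(vapply(crops, `[[`, 0, "rainfed_peak") + irrigated_boost +
            5 * noise_sd > 0.95)) {
    stop("rainfed_peak + irrigated_boost + noise headroom must stay below ",
         "0.95 NDVI", call. = FALSE)
  }
  if (base_ndvi - 5 * noise_sd < -1) stop("base_ndvi too low", call. = FALSE)
  structure(as.list(environment()), class = "scene_config")
}

# double-logistic seasonal shape, peak-normalised to 1 over the year
season_shape <- function(t, sowing, duration, steep = 1.5) {
  g <- 1 / (1 + exp(-steep * (t - (sowing + 1.5)))) *
    1 / (1 + exp(steep * (t - (sowing + duration - 0.5))))
  g / max(g)
}

# LULC legend used by generated scenes
scene_lulc_legend <- c(kharif_crop = 1L, rabi_crop = 2L, zaid_crop = 3L,
                       double_crop = 4L, other = 9L)

#' Generate a synthetic scene bundle
#'
#' Draws the per-pixel land state (non-agricultural / crop / steep terrain /
#' irrigated), builds each cropped pixel's NDVI profile as a double-logistic
#' seasonal curve (irrigated pixels get the rainfed peak plus the configured
#' boost), adds seeded Gaussian noise, and synthesizes RED/NIR reflectance
#' stacks consistent with the NDVI by construction
#' (`NDVI = (NIR - RED) / (NIR + RED)` holds composite-wise): RED tracks the
#' canopy state and NIR is solved from the target NDVI, both staying in
#' `[0, 1]`.  The same configuration (including seed) always yields a
#' bit-identical bundle.
#'
#' @param config a [scene_config()].
#' @return list of class `scene_bundle`: `ndvi` ([ndvi_stack()]), `red`,
#'   `nir` (arrays), `lulc`, `slope`, `zones` (maps), `zone_polygons`,
#'   `truth` (data frame: row, col, lulc, crop, irrigated, steep, sown),
#'   `lookup` (crop lookup table), `ag_codes`, `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  cfg <- config
  nr <- cfg$n_rows; nc <- cfg$n_cols; nt <- cfg$n_composites
  npix <- nr * nc
  grid <- grid_spec(nr, nc, pixel_size = cfg$pixel_size, crs_id = cfg$crs_id)
  crop_names <- names(cfg$crops)

  withr::with_seed(cfg$seed, {
    nonag <- stats::runif(npix) < cfg$frac_nonagricultural
    crop_idx <- sample.int(length(cfg$crops), npix, replace = TRUE)
    steep <- stats::runif(npix) < cfg$frac_steep
    irrigated <- !nonag & !steep & stats::runif(npix) < cfg$frac_irrigated
    # drawn unconditionally so scenarios share the pixel identities
    unsown_draw <- stats::runif(npix)
    noise <- matrix(stats::rnorm(npix * nt, sd = cfg$noise_sd), npix, nt)
    slope_flat <- stats::runif(npix, 0, 8)
    slope_steep <- stats::runif(npix, 22, 35)
  })
  unsown <- irrigated & unsown_draw < cfg$sown_reduction
  irrigated <- irrigated & !unsown
  cropped <- !nonag & !unsown

  tseq <- seq_len(nt) - 1
  shapes <- lapply(cfg$crops, function(cr)
    season_shape(tseq, cr$sowing, cr$duration))
  ndvi <- matrix(cfg$base_ndvi, npix, nt)
  gfull <- matrix(0, npix, nt)
  for (k in seq_along(cfg$crops)) {
    sel <- cropped & crop_idx == k
    if (!any(sel)) next
    peak_rf <- cfg$crops[[k]]$rainfed_peak * (1 - cfg$drought_deficit)
    peak <- ifelse(irrigated[sel],
                   cfg$crops[[k]]$rainfed_peak + cfg$irrigated_boost,
                   peak_rf)
    g <- shapes[[k]]
    ndvi[sel, ] <- cfg$base_ndvi +
      outer(peak - cfg$base_ndvi, g)
    gfull[sel, ] <- matrix(g, sum(sel), nt, byrow = TRUE)
  }
  ndvi <- ndvi + noise
  ndvi <- pmin(pmax(ndvi, -0.99), 0.99)

  red <- 0.10 - 0.06 * gfull
  nir <- red * (1 + ndvi) / (1 - ndvi)
  nir <- pmin(pmax(nir, 0), 1)

  season_code <- c(Kharif = 1L, Rabi = 2L, Zaid = 3L, Annual = 4L)
  lulc_codes <- ifelse(nonag, scene_lulc_legend[["other"]],
                       season_code[vapply(cfg$crops, `[[`, "", "season")][crop_idx])
  slope_vals <- ifelse(steep, slope_steep, slope_flat)

  to_mat <- function(v) matrix(v, nr, nc)        # pixel vectors are row-major-free
  to_arr <- function(m) array(m, c(nr, nc, nt))  # column-major fill per band

  dates <- seq(parse_water_year(cfg$water_year)$start, by = 16,
               length.out = nt)
  bundle <- list(
    ndvi = ndvi_stack(grid, to_arr(ndvi), dates, cfg$water_year),
    red = to_arr(red),
    nir = to_arr(nir),
    lulc = categorical_map(grid, to_mat(lulc_codes),
                           legend = scene_lulc_legend),
    slope = scalar_map(grid, to_mat(slope_vals), units = "percent"),
    zones = categorical_map(grid, matrix(1L, nr, nc)),
    zone_polygons = list(list(
      id = 1L, name = "zone-1",
      rings = list(cbind(c(grid$origin_x, grid$origin_x + nc * cfg$pixel_size,
                           grid$origin_x + nc * cfg$pixel_size, grid$origin_x,
                           grid$origin_x),
                         c(grid$origin_y, grid$origin_y,
                           grid$origin_y - nr * cfg$pixel_size,
                           grid$origin_y - nr * cfg$pixel_size,
                           grid$origin_y))))),
    truth = data.frame(
      row = rep(seq_len(nr), times = nc),
      col = rep(seq_len(nc), each = nr),
      lulc = as.integer(lulc_codes),
      crop = ifelse(cropped, crop_names[crop_idx], NA_character_),
      irrigated = irrigated,
      steep = steep,
      sown = cropped,
      stringsAsFactors = FALSE),
    lookup = default_crop_lookup(cfg),
    ag_codes = unname(season_code),
    config = cfg)
  class(bundle) <- "scene_bundle"
  bundle
}

#' Synthetic crop lookup table matching a scene configuration
#'
#' A documented, non-authoritative lookup table consistent with the
#' generator: for each crop, the season, a duration interval bracketing the
#' generated season length, and a height interval spanning the rainfed to
#' irrigated peak range.  Intended for testing and demonstration; real
#' applications supply a literature-derived table per agroecological zone.
#'
#' @param config a [scene_config()].
#' @param zone_id zone the entries apply to (default 1).
#' @return lookup data frame (see [read_crop_lookup()]).
#' @export
default_crop_lookup <- function(config, zone_id = 1L) {
  rows <- lapply(seq_along(config$crops), function(k) {
    cr <- config$crops[[k]]
    h_lo <- scale_height(max(0.1, cr$rainfed_peak *
                               (1 - config$drought_deficit) - 0.15))
    data.frame(zone_id = zone_id, crop_name = names(config$crops)[k],
               season = cr$season,
               height_min = floor(h_lo), height_max = 100,
               duration_min = max(1L, cr$duration - 5L),
               duration_max = cr$duration + 5L,
               priority = k, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Drought scenario of a configured scene
#'
#' Scales rainfed peak NDVI down by `deficit` while irrigated peaks stay
#' unchanged (groundwater-buffered irrigation), optionally leaving a fraction
#' of otherwise-irrigated pixels unsown (flat profile), the mechanism behind
#' drought-year declines in mapped irrigated area.  Pixel identities are
#' shared with the base scene generated from the same configuration, so
#' scenario and base bundles are directly comparable; `deficit = 0` with
#' `sown_reduction = 0` reproduces the base scene exactly.
#'
#' @param config a [scene_config()].
#' @param deficit rainfed peak reduction fraction in `[0, 1]`.
#' @param sown_reduction fraction of irrigated pixels left unsown.
#' @return a scene bundle (see [generate_scene()]).
#' @export
scenario_drought <- function(config, deficit, sown_reduction = 0) {
  stopifnot(inherits(config, "scene_config"),
            deficit >= 0, deficit <= 1,
            sown_reduction >= 0, sown_reduction <= 1)
  cfg <- config
  cfg$drought_deficit <- deficit
  cfg$sown_reduction <- sown_reduction
  generate_scene(cfg)
}

#' Write a scene bundle to disk
#'
#' Emits the rasters (TIFF + sidecar via [write_raster()]), the zone polygons
#' as GeoJSON, and the truth and lookup tables as CSV, i.e. exactly the
#' formats the pipeline consumes.
#'
#' @param bundle a scene bundle from [generate_scene()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(bundle, dir) {
  stopifnot(inherits(bundle, "scene_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(bundle$ndvi, file.path(dir, "ndvi.tif"))
  write_raster(bundle$lulc, file.path(dir, "lulc.tif"))
  write_raster(bundle$slope, file.path(dir, "slope.tif"))
  write_raster(bundle$zones, file.path(dir, "zones.tif"))
  gj <- list(type = "FeatureCollection", features = lapply(
    bundle$zone_polygons, function(z) list(
      type = "Feature",
      properties = list(zone_id = z$id, name = z$name),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(
                        seq_len(nrow(z$rings[[1]])),
                        function(i) as.list(z$rings[[1]][i, ])))))))
  jsonlite::write_json(gj, file.path(dir, "zones.geojson"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$lookup, file.path(dir, "lookup.csv"),
                   row.names = FALSE)
  invisible(dir)
}
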