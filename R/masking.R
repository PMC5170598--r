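#' Mask of potentially irrigable agricultural land
#'
#' A pixel is retained when its land-cover code is one of the declared
#' agriculture codes *and* its slope does not exceed the threshold (default
#' 20%, steeper terrain is masked out).  Pixels missing in either layer are
#' excluded.  All seasonal cropland codes (Kharif/Rabi/Zaid/double-cropped)
#' are normally passed together: the mask is season-agnostic; seasons are
#' handled later by the phenology stage.
#'
#' @param lulc a [categorical_map()] of land use / land cover.
#' @param ag_codes integer codes counting as agriculture.
#' @param slope a [scalar_map()] of slope in percent, co-registered with
#'   `lulc`.
#' @param slope_threshold_pct maximum retained slope in percent (default 20).
#' @return object of class `mask_layer`: `list(grid, include)` with a logical
#'   matrix `include`.
#' @export
agricultural_mask <- function(lulc, ag_codes, slope,
                              slope_threshold_pct = 20) {
  stopifnot(inherits(lulc, "categorical_map"), inherits(slope, "scalar_map"))
  if (!length(ag_codes)) stop("ag_codes must be non-empty", call. = FALSE)
  if (!is.numeric(slope_threshold_pct) || slope_threshold_pct < 0) {
    stop("slope_threshold_pct must be non-negative", call. = FALSE)
  }
  stop_if_grid_mismatch(lulc$grid, slope$grid, "lulc and slope")
  include <- !is.na(lulc$codes) & lulc$codes %in% as.integer(ag_codes) &
    !is.na(slope$values) & slope$values <= slope_threshold_pct
  structure(list(grid = lulc$grid, include = include), class = "mask_layer")
}

#' @export
print.mask_layer <- function(x, ...) {
  cat(sprintf("<mask_layer> %d of %d pixels included\n",
              sum(x$include), length(x$include)))
  invisible(x)
}

#' Partition the masked extent by agroecological zone
#'
#' Every included pixel is assigned to exactly one zone; zones are processed
#' separately downstream (training, signatures, thresholds).  Zones may be
#' given as an integer zone map or as polygons (pixel-center membership rule,
#' overlapping polygons are an error).  Included pixels covered by no zone are
#' dropped and counted in the result.
#'
#' @param mask a `mask_layer` from [agricultural_mask()].
#' @param zones a [categorical_map()] of zone ids, or a polygon list as read
#'   by [read_zones_geojson()].
#' @return object of class `zone_partition`: `list(zone_ids, pixels,
#'   n_dropped)` where `pixels` is a named list of two-column (row, col)
#'   index matrices (1-based), pairwise disjoint.
#' @export
partition_by_zone <- function(mask, zones) {
  stopifnot(inherits(mask, "mask_layer"))
  if (!inherits(zones, "categorical_map")) {
    zones <- zones_to_map(zones, mask$grid)
  }
  stop_if_grid_mismatch(mask$grid, zones$grid, "mask and zones")
  inc <- which(mask$include, arr.ind = TRUE)
  if (!nrow(inc)) {
    return(structure(list(zone_ids = integer(), pixels = list(),
                          n_dropped = 0L), class = "zone_partition"))
  }
  z <- zones$codes[inc]
  dropped <- is.na(z)
  if (any(dropped)) {
    message("partition_by_zone: ", sum(dropped),
            " masked pixel(s) outside all zones were dropped")
  }
  keep <- !dropped
  ids <- sort(unique(z[keep]))
  pixels <- lapply(ids, function(id) inc[keep & z == id, , drop = FALSE])
  names(pixels) <- as.character(ids)
  structure(list(zone_ids = ids, pixels = pixels,
                 n_dropped = sum(dropped)),
            class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf("<zone_partition> %d zone(s), %s pixels, %d dropped\n",
              length(x$zone_ids),
              paste(vapply(x$pixels, nrow, 1L), collapse = "+"),
              x$n_dropped))
  invisible(x)
}
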