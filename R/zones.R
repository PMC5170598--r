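#' Read zone or administrative polygons from GeoJSON
#'
#' Parses a GeoJSON FeatureCollection of Polygon / MultiPolygon features into
#' the simple polygon list used by [zones_to_map()] and [aggregate_area()].
#' The zone identifier is taken from the feature property `zone_id`, `id` or
#' `name` (first present); otherwise the feature index is used.  Only outer
#' rings are honoured; holes are not supported.
#'
#' @param path path to a GeoJSON file.
#' @return list of zones, each `list(id, name, rings)` where `rings` is a list
#'   of two-column coordinate matrices.
#' @export
read_zones_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                 call. = FALSE)
  lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    props <- f$properties %||% list()
    nm <- props$zone_id %||% props$id %||% props$name %||% i
    geom <- f$geometry
    ring_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    }
    rings <- switch(geom$type,
      Polygon = list(ring_mat(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(poly)
        ring_mat(poly[[1]])),
      stop("unsupported geometry type '", geom$type, "' in feature ", i,
           call. = FALSE))
    list(id = i, name = as.character(nm), rings = rings)
  })
}

#' Rasterize zone polygons by the pixel-center rule
#'
#' A pixel belongs to a zone when its center lies inside one of the zone's
#' rings (points on an edge count as inside).  Pixels whose center falls in
#' two or more zones raise an error naming the offending zones; pixels outside
#' every zone become `NA`.
#'
#' @param zones polygon list from [read_zones_geojson()] (or built in code).
#' @param grid the analysis [grid_spec()].
#' @return a [categorical_map()] of zone ids with a name legend.
#' @export
zones_to_map <- function(zones, grid) {
  stopifnot(is.list(zones), length(zones) >= 1L, inherits(grid, "grid_spec"))
  ctr <- pixel_centers(grid)
  codes <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  # row-major center order must match matrix filling
  idx_r <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  idx_c <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  for (z in zones) {
    inside <- rep(FALSE, nrow(ctr))
    for (ring in z$rings) {
      inside <- inside | pracma::inpolygon(ctr[, 1], ctr[, 2],
                                           ring[, 1], ring[, 2],
                                           boundary = TRUE)
    }
    hit <- which(inside)
    prev <- codes[cbind(idx_r[hit], idx_c[hit])]
    clash <- hit[!is.na(prev)]
    if (length(clash)) {
      stop("overlapping zone polygons: zone ", z$id, " ('", z$name,
           "') overlaps zone(s) ",
           paste(unique(prev[!is.na(prev)]), collapse = ", "),
           " on ", length(clash), " pixel(s)", call. = FALSE)
    }
    codes[cbind(idx_r[hit], idx_c[hit])] <- z$id
  }
  legend <- stats::setNames(vapply(zones, `[[`, 1L, "id"),
                            vapply(zones, `[[`, "", "name"))
  categorical_map(grid, codes, legend = legend)
}
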