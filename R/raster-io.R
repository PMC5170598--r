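#' Write a raster layer or stack to disk
#'
#' Rasters are written as multi-page TIFF files (one page per band, band order
#' = composite date order) with a JSON sidecar `<path>.aux.json` carrying the
#' georeferencing (grid size, origin, pixel size, CRS id, nodata), band dates,
#' units/legend and the value encoding.  TIFF samples can only represent
#' `[0, 1]`, so values are stored linearly rescaled into that interval with the
#' stored value 0 reserved for nodata; the sidecar declares the mapping so
#' [read_raster()] inverts it.  Categorical and 0/1 irrigation maps use 16-bit
#' integer samples and round-trip exactly; float layers use 32-bit samples and
#' round-trip to better than 1e-6 for NDVI-range data.  Binary irrigation maps
#' are single-band integer rasters with in-extent values {0, 1}.
#'
#' @param x an [ndvi_stack()], [categorical_map()], [scalar_map()] or
#'   [irrigation_map()].
#' @param path output file path (`.tif` suggested); the sidecar is written
#'   next to it.
#' @param encoding `"float32"` (default for continuous layers), `"int16"`
#'   (integer-scaled NDVI, scale factor 1e-4, the common archive convention)
#'   or `"code16"` (categorical/binary, forced for those classes).
#' @param metadata named list merged into the sidecar (e.g. a config hash).
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, encoding = NULL, metadata = list()) {
  kind <- class(x)[1]
  if (!kind %in% c("ndvi_stack", "categorical_map", "scalar_map",
                   "irrigation_map")) {
    stop("cannot write object of class ", kind, call. = FALSE)
  }
  vals <- raster_values(x)
  if (is.matrix(vals)) vals <- array(vals, c(dim(vals), 1L))
  integer_kind <- kind %in% c("categorical_map", "irrigation_map")
  if (is.null(encoding)) encoding <- if (integer_kind) "code16" else "float32"
  if (integer_kind && encoding != "code16") {
    stop("categorical and irrigation maps must use encoding 'code16'",
         call. = FALSE)
  }
  n_t <- dim(vals)[3]
  enc <- switch(encoding,
    code16 = {
      v <- vals
      if (any(v < 0L | v > 65533L, na.rm = TRUE)) {
        stop("codes outside the storable range 0..65533", call. = FALSE)
      }
      list(type = "code16", bits = 16L,
           pages = lapply(seq_len(n_t), function(i) {
             m <- (vals[, , i] + 1) / 65535
             m[is.na(m)] <- 0
             m
           }))
    },
    int16 = {
      ints <- round(vals / 1e-4)
      if (any(abs(ints) > 32000, na.rm = TRUE)) {
        stop("values outside the int16 scaled range", call. = FALSE)
      }
      list(type = "int16", bits = 16L, scale_factor = 1e-4, int_offset = 32001L,
           pages = lapply(seq_len(n_t), function(i) {
             m <- (round(vals[, , i] / 1e-4) + 32001) / 65535
             m[is.na(m)] <- 0
             m
           }))
    },
    float32 = {
      fin <- vals[is.finite(vals)]
      lo <- if (length(fin)) min(fin) else 0
      hi <- if (length(fin)) max(fin) else 1
      if (hi <= lo) hi <- lo + 1
      list(type = "float32", bits = 32L, value_min = lo, value_max = hi,
           pages = lapply(seq_len(n_t), function(i) {
             m <- 0.0625 + 0.9375 * (vals[, , i] - lo) / (hi - lo)
             m[is.na(m)] <- 0
             m
           }))
    },
    stop("unknown encoding '", encoding, "'", call. = FALSE)
  )
  ok <- tryCatch(
    tiff::writeTIFF(enc$pages, path, bits.per.sample = enc$bits),
    error = function(e) stop("cannot write '", path, "': ", conditionMessage(e),
                             call. = FALSE))
  sidecar <- list(
    kind = kind,
    grid = x$grid[c("n_rows", "n_cols", "pixel_size", "origin_x", "origin_y",
                    "crs_id", "nodata")],
    n_bands = n_t,
    encoding = enc[setdiff(names(enc), "pages")]
  )
  if (kind == "ndvi_stack") {
    sidecar$dates <- format(x$dates)
    sidecar$water_year <- x$water_year
  }
  if (kind == "irrigation_map") sidecar$water_year <- x$water_year
  if (kind == "scalar_map") sidecar$units <- x$units
  if (kind == "categorical_map" && !is.null(x$legend)) {
    sidecar$legend <- as.list(x$legend)
  }
  if (length(metadata)) sidecar$metadata <- metadata
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Read a raster layer or stack written by [write_raster()]
#'
#' Restores the object class, grid metadata and values from the TIFF and its
#' JSON sidecar.  Integer-scaled encodings (scale factor 1e-4) are converted
#' to NDVI floats automatically.  A bare TIFF without sidecar is accepted with
#' a warning: it is returned as a [scalar_map()] on a unit grid with no nodata
#' declared (no value treated as missing).
#'
#' @param path file path.
#' @param band_selection optional integer vector of band indices (1-based) to
#'   retain, in the order given must be increasing.
#' @return an [ndvi_stack()], [categorical_map()], [scalar_map()] or
#'   [irrigation_map()].
#' @export
read_raster <- function(path, band_selection = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) {
    stop("bands of '", path, "' have mismatched grids", call. = FALSE)
  }
  sc_file <- sidecar_path(path)
  if (!file.exists(sc_file)) {
    warning("no sidecar for '", path,
            "'; returning raw values on a unit grid with no declared nodata")
    g <- grid_spec(nrow(pages[[1]]), ncol(pages[[1]]), pixel_size = 1,
                   crs_id = "unknown", nodata = NA_real_)
    vals <- pages[[1]]
    return(scalar_map(g, vals, units = ""))
  }
  sc <- jsonlite::read_json(sc_file, simplifyVector = TRUE)
  if (sc$n_bands != length(pages)) {
    stop("sidecar declares ", sc$n_bands, " bands but file has ",
         length(pages), call. = FALSE)
  }
  if (is.null(band_selection)) band_selection <- seq_along(pages)
  stopifnot(all(band_selection >= 1L), all(band_selection <= length(pages)))
  g <- grid_spec(sc$grid$n_rows, sc$grid$n_cols,
                 pixel_size = sc$grid$pixel_size,
                 origin_x = sc$grid$origin_x, origin_y = sc$grid$origin_y,
                 crs_id = sc$grid$crs_id, nodata = sc$grid$nodata)
  decode <- function(m) {
    na <- m == 0
    out <- switch(sc$encoding$type,
      code16 = round(m * 65535) - 1,
      int16 = (round(m * 65535) - sc$encoding$int_offset) *
        sc$encoding$scale_factor,
      float32 = sc$encoding$value_min +
        (m - 0.0625) / 0.9375 *
          (sc$encoding$value_max - sc$encoding$value_min),
      stop("unknown encoding in sidecar: ", sc$encoding$type, call. = FALSE))
    out[na] <- NA
    out
  }
  mats <- lapply(pages[band_selection], decode)
  vals <- array(unlist(mats), c(dim(mats[[1]]), length(mats)))
  switch(sc$kind,
    ndvi_stack = ndvi_stack(g, vals, as.Date(sc$dates[band_selection]),
                            sc$water_year),
    categorical_map = categorical_map(
      g, matrix(as.integer(round(vals[, , 1])), g$n_rows, g$n_cols),
      legend = if (!is.null(sc$legend)) unlist(sc$legend)),
    scalar_map = scalar_map(g, vals[, , 1], units = sc$units %||% ""),
    irrigation_map = irrigation_map(
      g, matrix(as.integer(round(vals[, , 1])), g$n_rows, g$n_cols),
      water_year = sc$water_year %||% ""),
    stop("unknown raster kind in sidecar: ", sc$kind, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stack single-date NDVI composites into a water-year NDVIC
#'
#' Retains exactly the composites whose *start* date falls inside the water
#' year (June 1 of year Y to May 31 of year Y+1), sorts them by date, and
#' stacks them into an [ndvi_stack()].  No smoothing is applied to the
#' composites.  The result does not depend on the input order.
#'
#' @param composites list of single-band layers: [scalar_map()] objects or
#'   plain matrices sharing one grid.
#' @param dates composite start dates, parallel to `composites`.
#' @param water_year water-year label such as `"2000-01"`.
#' @param grid required when `composites` are plain matrices.
#' @return an [ndvi_stack()] with `T` = number of in-window composites.
#' @export
build_ndvic <- function(composites, dates, water_year, grid = NULL) {
  stopifnot(is.list(composites), length(composites) == length(dates),
            length(composites) >= 1L)
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("composite dates must be parseable", call. = FALSE)
  mats <- lapply(composites, function(cm) {
    if (inherits(cm, "scalar_map")) {
      if (is.null(grid)) grid <<- cm$grid
      stop_if_grid_mismatch(grid, cm$grid, "composites")
      cm$values
    } else if (is.matrix(cm)) {
      cm
    } else stop("composites must be scalar_map objects or matrices",
                call. = FALSE)
  })
  if (is.null(grid)) stop("supply 'grid' when composites are plain matrices",
                          call. = FALSE)
  if (length(unique(lapply(mats, dim))) != 1L) {
    stop("composite grids differ", call. = FALSE)
  }
  wy <- parse_water_year(water_year)
  keep <- which(dates >= wy$start & dates <= wy$end)
  if (!length(keep)) {
    stop("no composites fall inside water year ", water_year, call. = FALSE)
  }
  keep <- keep[order(dates[keep])]
  if (anyDuplicated(dates[keep])) {
    stop("duplicate composite dates inside water year ", water_year,
         call. = FALSE)
  }
  vals <- array(unlist(mats[keep]),
                c(grid$n_rows, grid$n_cols, length(keep)))
  message("build_ndvic: stacked T=", length(keep), " composites for ",
          water_year)
  ndvi_stack(grid, vals, dates[keep], water_year)
}

#' Resample a layer onto the analysis grid
#'
#' Aggregates (or disaggregates) a categorical or scalar layer onto a target
#' grid in the same CRS.  Categorical layers are resampled by area-weighted
#' majority vote of the covered source cells (ties broken toward the lowest
#' code); scalar layers by area-weighted mean.  Source cells flagged `NA` are
#' ignored; target cells with no overlapping valid source cell become `NA`.
#' A CRS mismatch is an error: reprojection is out of scope.
#'
#' @param src a [categorical_map()] or [scalar_map()].
#' @param target a [grid_spec()].
#' @param rule `"majority"` (required for categorical) or `"mean"`.
#' @return a layer of the same class as `src` on `target`.
#' @export
align_to_grid <- function(src, target,
                          rule = c("majority", "mean")) {
  rule <- match.arg(rule)
  stopifnot(inherits(target, "grid_spec"))
  categorical <- inherits(src, "categorical_map")
  if (!categorical && !inherits(src, "scalar_map")) {
    stop("align_to_grid handles categorical_map and scalar_map layers",
         call. = FALSE)
  }
  if (categorical && rule != "majority") {
    stop("categorical layers must use rule 'majority'", call. = FALSE)
  }
  if (!identical(src$grid$crs_id, target$crs_id)) {
    stop("CRS mismatch ('", src$grid$crs_id, "' vs '", target$crs_id,
         "'); reprojection is not supported", call. = FALSE)
  }
  if (same_grid(src$grid, target)) return(src)

  sg <- src$grid
  vals <- raster_values(src)
  # 1-D overlap lengths between half-open target and source pixel intervals
  overlap_1d <- function(t_lo, t_hi, s_origin, s_step, s_n) {
    i0 <- max(1L, floor((t_lo - s_origin) / s_step) + 1L)
    i1 <- min(s_n, ceiling((t_hi - s_origin) / s_step))
    if (i0 > i1) return(NULL)
    idx <- i0:i1
    lo <- s_origin + (idx - 1) * s_step
    hi <- lo + s_step
    w <- pmin(hi, t_hi) - pmax(lo, t_lo)
    keep <- w > 1e-12
    if (!any(keep)) return(NULL)
    list(idx = idx[keep], w = w[keep])
  }
  ps_t <- target$pixel_size
  col_ov <- lapply(seq_len(target$n_cols), function(c) {
    x0 <- target$origin_x + (c - 1) * ps_t
    overlap_1d(x0, x0 + ps_t, sg$origin_x, sg$pixel_size, sg$n_cols)
  })
  # rows run north->south: measure distance below the origin_y
  row_ov <- lapply(seq_len(target$n_rows), function(r) {
    d0 <- (target$origin_y - sg$origin_y) * -1 + (r - 1) * ps_t
    overlap_1d(d0, d0 + ps_t, 0, sg$pixel_size, sg$n_rows)
  })
  if (all(vapply(col_ov, is.null, TRUE)) || all(vapply(row_ov, is.null, TRUE))) {
    stop("source and target grids do not overlap", call. = FALSE)
  }
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  for (r in seq_len(target$n_rows)) {
    ro <- row_ov[[r]]
    if (is.null(ro)) next
    for (c in seq_len(target$n_cols)) {
      co <- col_ov[[c]]
      if (is.null(co)) next
      block <- vals[ro$idx, co$idx, drop = FALSE]
      w <- outer(ro$w, co$w)
      ok <- !is.na(block)
      if (!any(ok)) next
      if (categorical) {
        tw <- tapply(w[ok], block[ok], sum)
        best <- max(tw)
        cand <- as.integer(names(tw)[tw >= best - 1e-12])
        out[r, c] <- min(cand)
      } else {
        out[r, c] <- sum(block[ok] * w[ok]) / sum(w[ok])
      }
    }
  }
  if (categorical) {
    categorical_map(target, matrix(as.integer(out), target$n_rows,
                                   target$n_cols), legend = src$legend)
  } else {
    scalar_map(target, out, units = src$units)
  }
}
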