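#' Space-time spiral curves in RED-NIR feature space
#'
#' For each crop/irrigation class, tracks the class mean RED and NIR
#' reflectance through the composite dates.  Irrigated vegetation plots in
#' the "greenness" corner (high NIR, low RED), rainfed crops drift toward
#' "brightness" and open water toward "wetness", so well-separated curves
#' indicate a spatially and temporally consistent classification.  When two
#' class ids are named in `compare`, a scalar separability is emitted: the
#' mean Euclidean distance between the two curves across dates.
#'
#' @param red,nir reflectance stacks (`n_rows x n_cols x T` arrays, values in
#'   `[0, 1]`) co-registered with `class_map`.
#' @param class_map a `crop_class_map` or [categorical_map()].
#' @param dates composite dates of length `T`.
#' @param compare optional vector of two class ids to summarise.
#' @return object of class `stsc_curves`: `list(curves, separability)`;
#'   `curves` has one row per class x date with columns `class_id`, `date`,
#'   `red`, `nir`, `n`.
#' @export
stsc_curves <- function(red, nir, class_map, dates, compare = NULL) {
  red <- if (is.array(red) && length(dim(red)) == 3L) red else
    stop("red must be a 3-D reflectance array", call. = FALSE)
  nir <- if (is.array(nir) && length(dim(nir)) == 3L) nir else
    stop("nir must be a 3-D reflectance array", call. = FALSE)
  stopifnot(identical(dim(red), dim(nir)), dim(red)[3] == length(dates))
  codes <- raster_values(class_map)
  stopifnot(identical(dim(codes), dim(red)[1:2]))
  ids <- sort(unique(codes[!is.na(codes) & codes > 0L]))
  if (!length(ids)) stop("class map contains no classes", call. = FALSE)
  rows <- list()
  for (id in ids) {
    sel <- !is.na(codes) & codes == id
    n <- sum(sel)
    for (t in seq_along(dates)) {
      rt <- red[, , t][sel]
      nt <- nir[, , t][sel]
      ok <- !is.na(rt) & !is.na(nt)
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        class_id = id, date = dates[t], red = mean(rt[ok]),
        nir = mean(nt[ok]), n = sum(ok))
    }
  }
  curves <- do.call(rbind, rows)
  sep <- NA_real_
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2L)
    a <- curves[curves$class_id == compare[1], ]
    b <- curves[curves$class_id == compare[2], ]
    if (!nrow(a) || !nrow(b)) {
      stop("compare class(es) absent from the map", call. = FALSE)
    }
    m <- merge(a, b, by = "date")
    sep <- mean(sqrt((m$red.x - m$red.y)^2 + (m$nir.x - m$nir.y)^2))
  }
  structure(list(curves = curves, separability = sep, compare = compare),
            class = "stsc_curves")
}

#' Irrigated-area totals and per-polygon fractions
#'
#' Converts the binary map to area (each 250 m pixel is 6.25 ha; 1 mha =
#' 1e6 ha) and, when polygons (e.g. taluks) are supplied, reports per unit the
#' irrigated pixel count divided by the masked agricultural pixel count
#' (pixel-center membership).  Units without agricultural pixels get an `NA`
#' fraction, flagged in the output.
#'
#' @param map an [irrigation_map()].
#' @param pixel_area_ha area of one pixel in hectares (default 6.25 for
#'   250 m).
#' @param polygons optional polygon list ([read_zones_geojson()] format) or a
#'   [categorical_map()] of unit ids.
#' @param mask optional `mask_layer` giving the agricultural denominator;
#'   without it the denominator is all unit pixels.
#' @return list with `total_ha`, `total_mha` and (with polygons) `by_unit`, a
#'   data frame `unit`, `n_pixels`, `n_agricultural`, `n_irrigated`,
#'   `irrigated_ha`, `fraction`.
#' @export
aggregate_area <- function(map, pixel_area_ha = 6.25, polygons = NULL,
                           mask = NULL) {
  stopifnot(inherits(map, "irrigation_map"), pixel_area_ha > 0)
  n_irr <- sum(map$labels == 1L, na.rm = TRUE)
  out <- list(total_ha = n_irr * pixel_area_ha,
              total_mha = n_irr * pixel_area_ha / 1e6)
  if (!is.null(polygons)) {
    units_map <- if (inherits(polygons, "categorical_map")) polygons else
      zones_to_map(polygons, map$grid)
    stop_if_grid_mismatch(map$grid, units_map$grid, "map and units")
    inc <- if (is.null(mask)) NULL else mask$include
    ids <- sort(unique(units_map$codes[!is.na(units_map$codes)]))
    by_unit <- do.call(rbind, lapply(ids, function(id) {
      sel <- !is.na(units_map$codes) & units_map$codes == id
      n_ag <- if (is.null(inc)) sum(sel) else sum(sel & inc)
      ni <- sum(map$labels[sel] == 1L, na.rm = TRUE)
      data.frame(unit = id, n_pixels = sum(sel), n_agricultural = n_ag,
                 n_irrigated = ni, irrigated_ha = ni * pixel_area_ha,
                 fraction = if (n_ag > 0) ni / n_ag else NA_real_)
    }))
    if (any(is.na(by_unit$fraction))) {
      message("aggregate_area: ", sum(is.na(by_unit$fraction)),
              " unit(s) have no agricultural pixels; fraction undefined")
    }
    out$by_unit <- by_unit
  }
  out
}

#' Validation statistics against survey tables
#'
#' Root-mean-square error and coefficient of determination between observed
#' (e.g. ground-survey net irrigated area) and predicted (map-derived) values.
#' R squared is the squared Pearson correlation, identical to the R squared of
#' the simple linear fit with intercept, and is invariant under positive
#' affine rescaling of either series; RMSE is in the units of the inputs
#' (mha for state tables).
#'
#' @param observed,predicted finite numeric vectors of equal length `>= 2`.
#' @return object of class `validation_result`: `list(n, rmse, r_squared,
#'   residuals)` with residuals `predicted - observed`.
#' @export
validation_stats <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted), length(observed) >= 2L,
            all(is.finite(observed)), all(is.finite(predicted)))
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  res <- predicted - observed
  structure(list(n = length(observed),
                 rmse = sqrt(mean(res^2)),
                 r_squared = stats::cor(observed, predicted)^2,
                 residuals = res),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> n=%d  RMSE=%.4f  R2=%.4f\n",
              x$n, x$rmse, x$r_squared))
  invisible(x)
}

#' First-difference and standardized anomaly series
#'
#' For an annual series (e.g. irrigated area or rainfall), computes the first
#' differences `x_t - x_{t-1}` and the standardized anomalies
#' `(x_t - mean) / sd` with the sample (n-1) standard deviation, so the
#' standardized output has mean 0 and unit standard deviation.
#'
#' @param values numeric series of length `>= 3`.
#' @param labels optional period labels (e.g. water years).
#' @return object of class `anomaly_series`: `list(labels, values,
#'   first_differences, standardized)`.
#' @export
anomaly_series <- function(values, labels = NULL) {
  stopifnot(is.numeric(values), length(values) >= 3L,
            all(is.finite(values)))
  s <- stats::sd(values)
  if (s == 0) stop("standard deviation is zero; anomalies undefined",
                   call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_along(values))
  structure(list(labels = labels, values = values,
                 first_differences = diff(values),
                 standardized = (values - mean(values)) / s),
            class = "anomaly_series")
}

#' Read a validation table
#'
#' Delimited table with one row per reporting unit (state) and numeric area
#' columns in mha.  The package ships `table3_des_modis_iwmi.csv` under
#' `inst/extdata/`: the state-wise mean net irrigated area 2000-2010 from the
#' ground survey (DES) next to the 250 m satellite product and the IWMI
#' product, used by the validation examples and tests.
#'
#' @param path CSV path; default the packaged state table.
#' @return data frame.
#' @export
read_validation_table <- function(path = system.file(
  "extdata", "table3_des_modis_iwmi.csv", package = "irrimap")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
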