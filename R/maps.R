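#' Water-year NDVI composite stack
#'
#' The central data object: per-pixel NDVI time series on a shared grid, one
#' layer per 16-day composite, stacked for one water year (June 1 of year Y
#' through May 31 of year Y+1; a full year has T = 23 composites).  Composites
#' are used as delivered, without temporal smoothing.
#'
#' @param grid a [grid_spec()].
#' @param values numeric array `n_rows x n_cols x T`; valid NDVI lies in
#'   `[-1, 1]`, missing pixels are `NA`.
#' @param dates `Date` vector of length T, the composite start dates, strictly
#'   increasing and inside the water year.
#' @param water_year label such as `"2000-01"` (June 2000 to May 2001).
#' @return An object of class `ndvi_stack`.
#' @export
ndvi_stack <- function(grid, values, dates, water_year) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L,
            dim(values)[1] == grid$n_rows, dim(values)[2] == grid$n_cols)
  n_t <- dim(values)[3]
  dates <- as.Date(dates)
  stopifnot(length(dates) == n_t, n_t >= 1L, !anyNA(dates))
  if (n_t > 1L && any(diff(as.numeric(dates)) <= 0)) {
    stop("composite dates must be strictly increasing", call. = FALSE)
  }
  wy <- parse_water_year(water_year)
  if (any(dates < wy$start | dates > wy$end)) {
    stop("composite dates fall outside water year ", water_year, call. = FALSE)
  }
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < -1 || max(v) > 1)) {
    stop("NDVI values must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(grid = grid, values = values, dates = dates,
                 water_year = water_year),
            class = "ndvi_stack")
}

#' @export
print.ndvi_stack <- function(x, ...) {
  cat(sprintf("<ndvi_stack> %d x %d x T=%d, water year %s (%s .. %s)\n",
              x$grid$n_rows, x$grid$n_cols, dim(x$values)[3], x$water_year,
              format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

# "2000-01" -> June 1 2000 .. May 31 2001
parse_water_year <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  y <- suppressWarnings(as.integer(sub("-.*$", "", label)))
  if (is.na(y)) stop("cannot parse water-year label '", label, "'", call. = FALSE)
  list(start = as.Date(sprintf("%d-06-01", y)),
       end = as.Date(sprintf("%d-05-31", y + 1L)))
}

#' Categorical raster layer
#'
#' Integer-coded map on the analysis grid: land use / land cover classes,
#' agroecological zone ids, or crop class ids.  Missing pixels are `NA`.
#'
#' @param grid a [grid_spec()].
#' @param codes integer matrix `n_rows x n_cols`.
#' @param legend optional named integer vector mapping labels to codes.
#' @return An object of class `categorical_map`.
#' @export
categorical_map <- function(grid, codes, legend = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(codes),
            nrow(codes) == grid$n_rows, ncol(codes) == grid$n_cols)
  storage.mode(codes) <- "integer"
  if (!is.null(legend)) {
    stopifnot(is.numeric(legend), !is.null(names(legend)))
    legend <- stats::setNames(as.integer(legend), names(legend))
    extra <- setdiff(unique(codes[!is.na(codes)]), legend)
    if (length(extra)) {
      stop("codes not in legend: ", paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(grid = grid, codes = codes, legend = legend),
            class = "categorical_map")
}

#' Scalar raster layer
#'
#' Per-pixel real values with stated units (slope in percent, peak NDVI,
#' surface reflectance, ...).
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix `n_rows x n_cols`; missing pixels `NA`.
#' @param units free-text unit string (e.g. `"percent"`, `"ndvi"`).
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(grid, values, units = "") {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values, units = units),
            class = "scalar_map")
}

#' Binary irrigated-area map
#'
#' The pipeline's product: 1 = irrigated, 0 = not irrigated, for one water
#' year.  A 250 m pixel counts as fully irrigated under partial or full
#' irrigation (binary product semantics); each such pixel represents 6.25 ha.
#'
#' @param grid a [grid_spec()].
#' @param labels integer matrix of 0/1 (`NA` allowed outside the analysis
#'   extent).
#' @param water_year water-year label.
#' @return An object of class `irrigation_map`.
#' @export
irrigation_map <- function(grid, labels, water_year = "") {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(labels),
            nrow(labels) == grid$n_rows, ncol(labels) == grid$n_cols)
  storage.mode(labels) <- "integer"
  bad <- labels[!is.na(labels)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    stop("irrigation labels must be 0 or 1", call. = FALSE)
  }
  structure(list(grid = grid, labels = labels, water_year = water_year),
            class = "irrigation_map")
}

#' @export
print.irrigation_map <- function(x, ...) {
  cat(sprintf("<irrigation_map> %d x %d, %d irrigated pixels (%s)\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$labels == 1L, na.rm = TRUE),
              x$water_year))
  invisible(x)
}

raster_values <- function(x) {
  switch(class(x)[1],
         ndvi_stack = x$values,
         categorical_map = x$codes,
         scalar_map = x$values,
         irrigation_map = x$labels,
         mask_layer = x$include,
         crop_class_map = x$codes,
         stop("not a raster object: ", class(x)[1], call. = FALSE))
}
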