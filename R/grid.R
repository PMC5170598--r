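#' Georeferenced grid specification
#'
#' A `grid_spec` describes the regular, north-up analysis grid shared by all
#' raster layers: number of rows/columns, the map coordinates of the upper-left
#' corner, the (square) pixel size in map units, a CRS identifier and the
#' nodata sentinel used in files.  Pixel `(r, c)` (1-based in R) covers the
#' half-open square
#' `[origin_x + (c-1)*ps, origin_x + c*ps) x (origin_y - r*ps, origin_y - (r-1)*ps]`,
#' so row 1 is the northernmost row.  The nominal pixel size is 250 m, for
#' which one pixel represents 6.25 ha.
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param pixel_size pixel edge length in map units (default 250).
#' @param origin_x,origin_y map coordinates of the upper-left grid corner.
#' @param crs_id free-text identifier of the coordinate reference system.
#'   Layers are only combined when their `crs_id` match; reprojection is
#'   refused, not attempted.
#' @param nodata sentinel written to files for missing pixels (in R, missing
#'   pixels are `NA`).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, pixel_size = 250,
                      origin_x = 0, origin_y = n_rows * pixel_size,
                      crs_id = "local-meters", nodata = -9999) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L,
            is.finite(n_rows), is.finite(n_cols),
            n_rows > 0L, n_cols > 0L,
            is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0,
            is.numeric(origin_x), is.numeric(origin_y),
            is.character(crs_id), length(crs_id) == 1L)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 pixel_size = as.numeric(pixel_size),
                 origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 crs_id = crs_id, nodata = as.numeric(nodata)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, size %g, origin (%g, %g), CRS '%s'\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y,
              x$crs_id))
  invisible(x)
}

#' Test whether two grids are identical
#'
#' Grids are the same when dimensions, pixel size, origin and CRS agree
#' (coordinates to a small tolerance).
#'
#' @param a,b `grid_spec` objects.
#' @param tol numeric tolerance on coordinates and pixel size.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$pixel_size - b$pixel_size) <= tol &&
    abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol &&
    identical(a$crs_id, b$crs_id)
}

#' Map coordinates of pixel centers
#'
#' @param grid a `grid_spec`.
#' @param rows,cols 1-based pixel indices (vectors of equal length); defaults
#'   give every pixel in row-major order.
#' @return two-column matrix of (x, y) center coordinates.
#' @export
pixel_centers <- function(grid,
                          rows = rep(seq_len(grid$n_rows), each = grid$n_cols),
                          cols = rep(seq_len(grid$n_cols), times = grid$n_rows)) {
  stopifnot(inherits(grid, "grid_spec"), length(rows) == length(cols))
  cbind(x = grid$origin_x + (cols - 0.5) * grid$pixel_size,
        y = grid$origin_y - (rows - 0.5) * grid$pixel_size)
}

stop_if_grid_mismatch <- function(a, b, what = "layers") {
  if (!identical(a$crs_id, b$crs_id)) {
    stop("CRS mismatch between ", what, " ('", a$crs_id, "' vs '", b$crs_id,
         "'); reprojection is not supported", call. = FALSE)
  }
  if (!same_grid(a, b)) {
    stop("grid mismatch between ", what,
         "; align layers with align_to_grid() first", call. = FALSE)
  }
  invisible(TRUE)
}
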