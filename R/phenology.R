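#' Scale peak NDVI to the 1-100 "height" descriptor
#'
#' Crops are described in the lookup table by an "average height": the peak
#' NDVI a crop attains during its season, linearly rescaled so that the
#' croppable NDVI range 0.1-0.8 maps onto 1-100.  Values below 0.1 clamp to 1
#' and above 0.8 to 100.
#'
#' @param peak_ndvi numeric vector of peak NDVI values.
#' @return numeric vector of heights in `[1, 100]`.
#' @export
scale_height <- function(peak_ndvi) {
  if (!is.numeric(peak_ndvi) || any(!is.finite(peak_ndvi))) {
    stop("peak_ndvi must be finite numeric", call. = FALSE)
  }
  v <- pmin(pmax(peak_ndvi, 0.1), 0.8)
  # clamp the output too: v - 0.1 can overshoot 0.7 by one ulp at v = 0.8
  pmin(pmax(1 + 99 * (v - 0.1) / 0.7, 1), 100)
}

#' Emergence and senescence from cumulative NDVI departure
#'
#' Departures from the profile mean are accumulated over the water year;
#' emergence is the composite where the cumulative departure is minimal (the
#' below-mean to above-mean turning point) and senescence the later composite
#' where it is maximal (the above-mean to below-mean crossing).  Ties take the
#' earliest composite.  Internal `NA` gaps are filled by linear interpolation
#' first; leading/trailing `NA`s take the nearest valid value.
#'
#' Returned indices are 0-based offsets into the composite sequence, matching
#' the numbering of 16-day composites within the water year.
#'
#' @param profile numeric vector of `T >= 3` NDVI values.
#' @param tol profiles whose cumulative departure never leaves `[-tol, tol]`
#'   carry no seasonal signal and are rejected.
#' @return named numeric vector `c(emergence, senescence)` (0-based), or
#'   `NULL` when the profile carries no season (constant profile, or no
#'   post-emergence maximum).
#' @export
cumulative_departure_dates <- function(profile, tol = 1e-9) {
  stopifnot(is.numeric(profile))
  n <- length(profile)
  if (n < 3L) stop("profile needs at least 3 composites", call. = FALSE)
  x <- fill_gaps(profile)
  if (anyNA(x)) return(NULL)
  cdep <- cumsum(x - mean(x))
  if (max(abs(cdep)) <= tol) return(NULL)   # constant: no seasonal signal
  e <- which.min(cdep)                      # earliest minimum
  if (e >= n) return(NULL)                  # nothing after emergence
  s <- e + which.max(cdep[(e + 1L):n])      # earliest later maximum
  if (cdep[s] <= cdep[e] + tol) return(NULL)
  c(emergence = e - 1L, senescence = s - 1L)
}

# linear interpolation across internal NA runs; edge NAs take nearest value
fill_gaps <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) < 2L) return(x)
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

longest_na_run <- function(x) {
  r <- rle(is.na(x))
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Default seasonal-pool windows
#'
#' The water year is cut into four pools of composite indices (0-based): the
#' first season FS (Kharif, roughly June-October), the second season SS
#' (Rabi, November-March), the intermediate season IS (Zaid, April-May) and
#' the complete season CMS spanning the whole year.  For a 23-composite year
#' the defaults are FS = 0..9, SS = 10..18, IS = 19..22; other stack lengths
#' scale the boundaries proportionally.  Windows are configurable per zone.
#'
#' @param n_composites stack length `T` (default 23).
#' @return named list of 0-based index vectors.
#' @export
default_season_pools <- function(n_composites = 23L) {
  stopifnot(n_composites >= 3L)
  b1 <- max(1L, round(10 / 23 * n_composites))
  b2 <- max(b1 + 1L, round(19 / 23 * n_composites))
  b2 <- min(b2, n_composites - 1L)
  list(FS = 0:(b1 - 1L),
       SS = b1:(b2 - 1L),
       IS = b2:(n_composites - 1L),
       CMS = 0:(n_composites - 1L))
}

pool_season_labels <- c(FS = "Kharif", SS = "Rabi", IS = "Zaid",
                        CMS = "Annual")

#' Per-pool season descriptors for one pixel profile
#'
#' For each seasonal pool window in which the cumulative-departure rule finds
#' a season (and the within-pool NDVI range exceeds `min_amplitude`), emits
#' one descriptor: emergence and senescence composite indices (0-based,
#' water-year frame), duration (senescence minus emergence, in composites),
#' the peak NDVI attained between emergence and senescence, and the scaled
#' height.  A flat profile yields an empty set.
#'
#' @param profile numeric NDVI profile of length `T`.
#' @param pools named list of 0-based composite windows
#'   (default [default_season_pools()]).
#' @param min_amplitude minimum NDVI range within a pool for a season to be
#'   considered (default 0.05, below typical composite noise for crops).
#' @return data frame with columns `pool`, `season`, `emergence_idx`,
#'   `senescence_idx`, `duration`, `peak_ndvi`, `height` (0 rows if none).
#' @export
extract_season_descriptors <- function(profile,
                                       pools = default_season_pools(length(profile)),
                                       min_amplitude = 0.05) {
  stopifnot(is.numeric(profile), is.list(pools))
  x <- fill_gaps(profile)
  out <- lapply(names(pools), function(pn) {
    idx <- pools[[pn]] + 1L
    if (length(idx) < 3L || min(idx) < 1L || max(idx) > length(x)) return(NULL)
    sub <- x[idx]
    if (anyNA(sub) || diff(range(sub)) < min_amplitude) return(NULL)
    es <- cumulative_departure_dates(sub)
    if (is.null(es)) return(NULL)
    off <- pools[[pn]][1]
    peak <- max(sub[(es["emergence"] + 1L):(es["senescence"] + 1L)])
    data.frame(pool = pn,
               season = unname(pool_season_labels[pn]),
               emergence_idx = unname(es["emergence"]) + off,
               senescence_idx = unname(es["senescence"]) + off,
               duration = unname(es["senescence"] - es["emergence"]),
               peak_ndvi = peak,
               height = scale_height(peak),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(pool = character(), season = character(),
                      emergence_idx = numeric(), senescence_idx = numeric(),
                      duration = numeric(), peak_ndvi = numeric(),
                      height = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' Regular lattice of training pixels
#'
#' Training samples are drawn on a deterministic square lattice with one
#' candidate every `round(spacing_m / pixel_size_m)` rows and columns
#' (every 16th pixel for 4 km spacing on a 250 m grid), intersected with the
#' agricultural mask.  The lattice is anchored at half the step so samples sit
#' away from the grid edge.
#'
#' @param mask a `mask_layer`.
#' @param spacing_m target sample spacing in meters (default 4000).
#' @param pixel_size_m pixel size in meters (default 250).
#' @return two-column matrix of (row, col) indices (1-based).
#' @export
select_training_pixels <- function(mask, spacing_m = 4000,
                                   pixel_size_m = 250) {
  stopifnot(inherits(mask, "mask_layer"))
  if (spacing_m < pixel_size_m) {
    stop("spacing_m must be at least the pixel size", call. = FALSE)
  }
  if (!any(mask$include)) stop("mask is empty", call. = FALSE)
  step <- max(1L, as.integer(round(spacing_m / pixel_size_m)))
  start <- as.integer(ceiling(step / 2))
  rows <- seq.int(start, nrow(mask$include), by = step)
  cols <- seq.int(start, ncol(mask$include), by = step)
  lattice <- as.matrix(expand.grid(row = rows, col = cols,
                                   KEEP.OUT.ATTRS = FALSE))
  keep <- mask$include[lattice]
  lattice[keep, , drop = FALSE]
}

#' Read a crop lookup table
#'
#' Delimited text, one row per (zone, crop): expected season, height interval
#' and duration interval, plus a priority (1 = evaluated first; thresholds
#' are applied hierarchically).  Columns: `zone_id, crop_name, season,
#' height_min, height_max, duration_min, duration_max, priority`.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_crop_lookup <- function(path) {
  lut <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_crop_lookup(lut)
}

validate_crop_lookup <- function(lut) {
  need <- c("zone_id", "crop_name", "season", "height_min", "height_max",
            "duration_min", "duration_max", "priority")
  miss <- setdiff(need, names(lut))
  if (length(miss)) {
    stop("lookup table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(lut$height_min <= lut$height_max),
            all(lut$duration_min <= lut$duration_max),
            all(lut$duration_min >= 1))
  lut
}

#' Assign a crop type from season descriptors
#'
#' Lookup entries for the zone are scanned in priority order; the first entry
#' whose season matches a descriptor's season label, whose duration interval
#' contains the descriptor's duration, and whose height interval contains the
#' descriptor's height wins.  No match returns `NA` (unassigned).  The
#' function is pure: identical inputs give identical output.
#'
#' @param descriptors data frame from [extract_season_descriptors()].
#' @param lookup lookup table (see [read_crop_lookup()]).
#' @param zone_id zone whose entries apply.
#' @return crop name, or `NA_character_`.
#' @export
assign_crop_type <- function(descriptors, lookup, zone_id) {
  lookup <- validate_crop_lookup(lookup)
  lut <- lookup[lookup$zone_id == zone_id, , drop = FALSE]
  if (!nrow(lut)) stop("lookup has no entries for zone ", zone_id,
                       call. = FALSE)
  if (!nrow(descriptors)) return(NA_character_)
  lut <- lut[order(lut$priority), , drop = FALSE]
  for (i in seq_len(nrow(lut))) {
    hit <- descriptors$season == lut$season[i] &
      descriptors$duration >= lut$duration_min[i] &
      descriptors$duration <= lut$duration_max[i] &
      descriptors$height >= lut$height_min[i] &
      descriptors$height <= lut$height_max[i]
    if (any(hit)) return(lut$crop_name[i])
  }
  NA_character_
}

#' Build labelled training samples for one zone
#'
#' Lattice pixels inside the zone are profiled; pixels with an `NA` gap longer
#' than `max_gap` composites are disqualified, remaining gaps are linearly
#' interpolated.  Each profile's season descriptors are matched against the
#' zone's lookup entries; pixels that receive a crop label become training
#' samples.
#'
#' @param ndvic an [ndvi_stack()].
#' @param pixels (row, col) matrix of candidate pixels (e.g. the lattice from
#'   [select_training_pixels()] restricted to the zone).
#' @param lookup crop lookup table.
#' @param zone_id zone identifier.
#' @param pools seasonal pool windows.
#' @param max_gap maximum tolerated `NA` run (composites, default 3).
#' @param min_amplitude see [extract_season_descriptors()].
#' @return list with `samples` (data frame: row, col, zone_id, crop) and
#'   `profiles` (matrix, one gap-filled profile per sample row).
#' @export
build_training_samples <- function(ndvic, pixels, lookup, zone_id,
                                   pools = default_season_pools(dim(ndvic$values)[3]),
                                   max_gap = 3L, min_amplitude = 0.05) {
  stopifnot(inherits(ndvic, "ndvi_stack"), is.matrix(pixels))
  keep_row <- integer()
  keep_col <- integer()
  crops <- character()
  profs <- list()
  for (i in seq_len(nrow(pixels))) {
    p <- ndvic$values[pixels[i, 1], pixels[i, 2], ]
    if (all(is.na(p)) || longest_na_run(p) > max_gap) next
    p <- fill_gaps(p)
    des <- extract_season_descriptors(p, pools, min_amplitude)
    crop <- assign_crop_type(des, lookup, zone_id)
    if (is.na(crop)) next
    keep_row <- c(keep_row, pixels[i, 1])
    keep_col <- c(keep_col, pixels[i, 2])
    crops <- c(crops, crop)
    profs[[length(profs) + 1L]] <- p
  }
  list(samples = data.frame(row = keep_row, col = keep_col,
                            zone_id = zone_id, crop = crops,
                            stringsAsFactors = FALSE),
       profiles = if (length(profs)) do.call(rbind, profs) else
         matrix(numeric(), 0L, dim(ndvic$values)[3]))
}
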