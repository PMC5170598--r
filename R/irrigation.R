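#' Class/pool NDVI statistics and the irrigation threshold
#'
#' For one crop class, takes the maximum per-pixel peak NDVI attained in each
#' of the class's `n` seasonal pools (`NDVI_imclass`) and derives the
#' decision-tree quantities:
#' \deqn{NDVI_{mclass} = \frac{1}{n}\sum_i NDVI_{imclass,i}, \qquad
#'       NDVI_{mp} = \min_i NDVI_{imclass,i},}
#' \deqn{MVCI = \frac{NDVI_{mp} - NDVI_{mclass}}{NDVI_{mclass}}, \qquad
#'       NDVI_{irclass} = MVCI \cdot NDVI_{mp} + NDVI_{mp}.}
#' `MVCI` is the mean vegetation condition index of the class: the relative
#' shortfall of the most stressed pool's ceiling from the class mean (as a
#' fraction; reporting it as a percentage is multiplication by 100).  It is
#' never positive, so `NDVI_irclass <= NDVI_mp <= NDVI_mclass`; with a single
#' pool (or all pools equal) MVCI is 0 and the threshold collapses to
#' `NDVI_mp`.
#'
#' @param ndvi_imclass numeric vector, one per-pool class maximum, `n >= 1`,
#'   values in `[-1, 1]`.
#' @param class_id optional class identifier carried through.
#' @param pool_ids optional pool labels, parallel to `ndvi_imclass`.
#' @return object of class `class_pool_stats` with fields `class_id`,
#'   `pool_ids`, `ndvi_imclass`, `ndvi_mclass`, `ndvi_mp`, `mvci`,
#'   `ndvi_irclass`.
#' @export
compute_class_pool_stats <- function(ndvi_imclass, class_id = NA_integer_,
                                     pool_ids = NULL) {
  stopifnot(is.numeric(ndvi_imclass), length(ndvi_imclass) >= 1L,
            all(is.finite(ndvi_imclass)))
  if (any(ndvi_imclass < -1 | ndvi_imclass > 1)) {
    stop("NDVI_imclass values must lie in [-1, 1]", call. = FALSE)
  }
  mclass <- mean(ndvi_imclass)
  if (mclass == 0) stop("NDVI_mclass is zero; MVCI undefined", call. = FALSE)
  mp <- min(ndvi_imclass)
  mvci <- (mp - mclass) / mclass
  structure(list(class_id = class_id,
                 pool_ids = pool_ids %||% seq_along(ndvi_imclass),
                 ndvi_imclass = ndvi_imclass,
                 ndvi_mclass = mclass,
                 ndvi_mp = mp,
                 mvci = mvci,
                 ndvi_irclass = mvci * mp + mp),
            class = "class_pool_stats")
}

#' @export
print.class_pool_stats <- function(x, ...) {
  cat(sprintf(
    "<class_pool_stats> class %s: n=%d pools, imclass [%s]\n  mclass %.4f  mp %.4f  MVCI %.4f  irclass %.4f\n",
    as.character(x$class_id), length(x$ndvi_imclass),
    paste(sprintf("%.3f", x$ndvi_imclass), collapse = ", "),
    x$ndvi_mclass, x$ndvi_mp, x$mvci, x$ndvi_irclass))
  invisible(x)
}

#' Split a class's pixels into condition subpools
#'
#' Seasonal pools of a crop class are its condition subclasses: groups of
#' pixels of the same crop whose seasonal peak NDVI sits at different levels
#' (stressed through unstressed).  Pixels are binned by quantiles of their
#' peak NDVI into at most `n_pools` groups; the per-pool maxima are the
#' `NDVI_imclass` inputs of [compute_class_pool_stats()], so the lowest
#' pool's maximum estimates the unirrigated ceiling `NDVI_mp`.  Pixels are
#' ranked by peak (ties broken by pixel order) and the ranking is cut into
#' `n_pools` equal-count groups, so the binning is deterministic and survives
#' heavily tied peak distributions.
#'
#' @param peaks numeric vector of per-pixel peak NDVI within a class.
#' @param n_pools target number of subpools (default 3).
#' @return integer vector of pool memberships in `1..n_pools`.
#' @export
condition_pools <- function(peaks, n_pools = 3L) {
  stopifnot(is.numeric(peaks), length(peaks) >= 1L, n_pools >= 1L)
  n <- length(peaks)
  if (n_pools == 1L || n == 1L) return(rep(1L, n))
  pos <- integer(n)
  pos[order(peaks)] <- seq_len(n)
  as.integer(ceiling(pos * n_pools / n))
}

#' Label irrigated pixels with the class threshold rule
#'
#' For every pixel assigned to a crop class, its `NDVI_iclass` value `v` is
#' the peak NDVI of its best pool (its water-year maximum).  The pixel is
#' labelled irrigated (1) when both decision-tree clauses hold:
#' `v >= max(NDVI_irclass, min_irclass)` (the class threshold, floored at 0.2
#' NDVI) and `v - NDVI_mp >= min_separation` (a minimum 0.15 NDVI gap above
#' the class's stressed-pool ceiling).  Unclassified and unmasked pixels are
#' labelled 0.  The irrigated set shrinks monotonically as either threshold
#' rises.
#'
#' @param ndvic an [ndvi_stack()].
#' @param class_map a `crop_class_map` from [classify_pixels()].
#' @param stats named list of [compute_class_pool_stats()] results, keyed by
#'   class id (as character); required for every class present in the map.
#' @param min_irclass NDVI floor on the class threshold (default 0.2).
#' @param min_separation minimum pixel-minus-`NDVI_mp` gap (default 0.15).
#' @return an [irrigation_map()].
#' @export
classify_irrigation <- function(ndvic, class_map, stats,
                                min_irclass = 0.2, min_separation = 0.15) {
  stopifnot(inherits(ndvic, "ndvi_stack"), inherits(class_map, "crop_class_map"))
  stop_if_grid_mismatch(ndvic$grid, class_map$grid, "ndvic and class map")
  grid <- ndvic$grid
  labels <- matrix(0L, grid$n_rows, grid$n_cols)
  px <- which(!is.na(class_map$codes) & class_map$codes > 0L, arr.ind = TRUE)
  if (nrow(px)) {
    cls <- class_map$codes[px]
    present <- unique(cls)
    missing <- present[!as.character(present) %in% names(stats)]
    if (length(missing)) {
      stop("no class_pool_stats for class id(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    v <- apply(px, 1L, function(p) {
      prof <- ndvic$values[p[1], p[2], ]
      if (all(is.na(prof))) NA_real_ else max(prof, na.rm = TRUE)
    })
    theta <- vapply(stats, function(s) max(s$ndvi_irclass, min_irclass), 0)
    mp <- vapply(stats, function(s) s$ndvi_mp, 0)
    k <- as.character(cls)
    irr <- !is.na(v) & v >= theta[k] & (v - mp[k]) >= min_separation
    labels[px] <- as.integer(irr)
  }
  irrigation_map(grid, labels, water_year = ndvic$water_year)
}

#' Default pipeline parameters
#'
#' All tunables of the end-to-end classification in one validated list.
#'
#' @param ag_codes LULC codes treated as agriculture.
#' @param slope_threshold_pct slope mask threshold in percent (default 20).
#' @param spacing_m training-lattice spacing in meters (default 4000).
#' @param min_members minimum training members per crop signature (default 3).
#' @param min_scm minimum accepted SCM score (default 0.5).
#' @param min_irclass NDVI floor on the irrigation threshold (default 0.2).
#' @param min_separation minimum NDVI gap over the stressed ceiling
#'   (default 0.15).
#' @param n_condition_pools condition subpools per class (default 3).
#' @param max_gap maximum NA run tolerated in training profiles (default 3).
#' @param min_amplitude minimum seasonal NDVI range (default 0.05).
#' @return named list of parameters.
#' @export
pipeline_params <- function(ag_codes = c(1L, 2L, 3L, 4L),
                            slope_threshold_pct = 20,
                            spacing_m = 4000,
                            min_members = 3L,
                            min_scm = 0.5,
                            min_irclass = 0.2,
                            min_separation = 0.15,
                            n_condition_pools = 3L,
                            max_gap = 3L,
                            min_amplitude = 0.05) {
  stopifnot(slope_threshold_pct >= 0, spacing_m > 0, min_members >= 1,
            min_scm >= -1, min_scm <= 1, min_irclass >= 0, min_irclass <= 1,
            min_separation >= 0, min_separation <= 2,
            n_condition_pools >= 1)
  list(ag_codes = as.integer(ag_codes),
       slope_threshold_pct = slope_threshold_pct,
       spacing_m = spacing_m, min_members = as.integer(min_members),
       min_scm = min_scm, min_irclass = min_irclass,
       min_separation = min_separation,
       n_condition_pools = as.integer(n_condition_pools),
       max_gap = as.integer(max_gap), min_amplitude = min_amplitude)
}

#' Run the full irrigated-area pipeline
#'
#' Executes, per agroecological zone: agricultural masking (LULC + slope),
#' lattice training-sample selection and lookup-table crop labelling,
#' end-member signature construction, SCM crop classification, condition
#' subpooling, Eq.-style threshold derivation and irrigated/rainfed
#' labelling.  Fully deterministic for fixed inputs and parameters.
#'
#' @param ndvic an [ndvi_stack()].
#' @param lulc a [categorical_map()] on the same grid.
#' @param slope a [scalar_map()] of slope percent on the same grid.
#' @param zones a zone [categorical_map()] or polygon list; `NULL` treats the
#'   whole grid as one zone.
#' @param lookup crop lookup table (data frame or CSV path).
#' @param params list from [pipeline_params()].
#' @return list of class `irrimap_result`: `irrigation` ([irrigation_map()]),
#'   `crops` (`crop_class_map`), `audit` (per-zone parameters, class-pool
#'   statistics and pixel tallies).
#' @export
run_pipeline <- function(ndvic, lulc, slope, zones = NULL, lookup,
                         params = pipeline_params()) {
  stopifnot(inherits(ndvic, "ndvi_stack"))
  if (is.character(lookup)) lookup <- read_crop_lookup(lookup)
  lookup <- validate_crop_lookup(lookup)
  grid <- ndvic$grid
  stop_if_grid_mismatch(grid, lulc$grid, "ndvic and lulc")
  stop_if_grid_mismatch(grid, slope$grid, "ndvic and slope")
  if (is.null(zones)) {
    zones <- categorical_map(grid, matrix(1L, grid$n_rows, grid$n_cols))
  }

  mask <- agricultural_mask(lulc, params$ag_codes, slope,
                            params$slope_threshold_pct)
  audit <- list(params = params, n_masked = sum(mask$include), zones = list())
  codes <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  scores <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  labels <- matrix(0L, grid$n_rows, grid$n_cols)
  legend <- integer()

  if (!any(mask$include)) {
    audit$note <- "agricultural mask is empty; all-zero irrigation map"
    result <- list(
      irrigation = irrigation_map(grid, labels, ndvic$water_year),
      crops = structure(list(grid = grid, codes = codes, scores = scores,
                             legend = legend), class = "crop_class_map"),
      audit = structure(audit, class = "irrimap_audit"))
    return(structure(result, class = c("irrimap_result", "list")))
  }

  part <- partition_by_zone(mask, zones)
  pools <- default_season_pools(dim(ndvic$values)[3])
  lattice <- select_training_pixels(mask, params$spacing_m,
                                    grid$pixel_size)
  next_id <- 0L

  for (zid in part$zone_ids) {
    zpix <- part$pixels[[as.character(zid)]]
    zinfo <- list(zone_id = zid, n_pixels = nrow(zpix))
    zmask <- structure(list(grid = grid,
                            include = matrix(FALSE, grid$n_rows, grid$n_cols)),
                       class = "mask_layer")
    zmask$include[zpix] <- TRUE
    zlat <- lattice[zmask$include[lattice], , drop = FALSE]
    if (!nrow(zlat) || !any(lookup$zone_id == zid)) {
      zinfo$note <- "no training lattice pixels or no lookup entries; zone skipped"
      codes[zpix] <- 0L
      audit$zones[[as.character(zid)]] <- zinfo
      next
    }
    tr <- build_training_samples(ndvic, zlat, lookup, zid, pools,
                                 params$max_gap, params$min_amplitude)
    zinfo$n_training <- nrow(tr$samples)
    zinfo$training_by_crop <- table(tr$samples$crop)
    if (nrow(tr$samples) < params$min_members) {
      zinfo$note <- "too few labelled training samples; zone left unclassified"
      codes[zpix] <- 0L
      audit$zones[[as.character(zid)]] <- zinfo
      next
    }
    sigs <- tryCatch(
      build_signatures(tr$profiles, tr$samples$crop, params$min_members),
      error = function(e) NULL)
    if (is.null(sigs)) {
      zinfo$note <- "no viable crop signature; zone left unclassified"
      codes[zpix] <- 0L
      audit$zones[[as.character(zid)]] <- zinfo
      next
    }
    # make class ids unique across zones
    for (i in seq_along(sigs)) sigs[[i]]$class_id <- next_id + i
    zinfo$dropped_signatures <- attr(sigs, "dropped")
    cmap <- classify_pixels(ndvic, sigs, zmask, params$min_scm)
    codes[zpix] <- cmap$codes[zpix]
    scores[zpix] <- cmap$scores[zpix]
    legend <- c(legend, cmap$legend)

    zstats <- list()
    zclass <- list()
    for (s in cmap$legend) {
      cpx <- which(cmap$codes == s, arr.ind = TRUE)
      if (!nrow(cpx)) next
      peaks <- apply(cpx, 1L, function(p)
        max(ndvic$values[p[1], p[2], ], na.rm = TRUE))
      pool_of <- condition_pools(peaks, params$n_condition_pools)
      imclass <- as.numeric(tapply(peaks, pool_of, max))
      zstats[[as.character(s)]] <- compute_class_pool_stats(
        imclass, class_id = s, pool_ids = sort(unique(pool_of)))
      zclass[[as.character(s)]] <- list(
        crop = names(cmap$legend)[match(s, cmap$legend)],
        n_pixels = nrow(cpx))
    }
    if (length(zstats)) {
      zimap <- classify_irrigation(ndvic, cmap, zstats,
                                   params$min_irclass, params$min_separation)
      labels[zpix] <- zimap$labels[zpix]
      for (s in names(zstats)) {
        zclass[[s]]$theta <- max(zstats[[s]]$ndvi_irclass, params$min_irclass)
        zclass[[s]]$n_irrigated <- sum(zimap$labels[codes == as.integer(s)],
                                       na.rm = TRUE)
      }
    }
    zinfo$class_stats <- zstats
    zinfo$classes <- zclass
    zinfo$n_unclassified <- sum(codes[zpix] == 0L, na.rm = TRUE)
    zinfo$n_irrigated <- sum(labels[zpix])
    audit$zones[[as.character(zid)]] <- zinfo
    next_id <- next_id + length(sigs)
  }

  audit$n_dropped_outside_zones <- part$n_dropped
  audit$n_irrigated <- sum(labels)
  result <- list(
    irrigation = irrigation_map(grid, labels, ndvic$water_year),
    crops = structure(list(grid = grid, codes = codes, scores = scores,
                           legend = legend), class = "crop_class_map"),
    audit = structure(audit, class = "irrimap_audit"))
  structure(result, class = c("irrimap_result", "list"))
}

#' @export
print.irrimap_audit <- function(x, ...) {
  cat("Irrigated-area pipeline audit\n")
  cat("  masked agricultural pixels:", x$n_masked, "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  for (zn in names(x$zones)) {
    z <- x$zones[[zn]]
    cat(sprintf("  zone %s: %d pixels", zn, z$n_pixels))
    if (!is.null(z$n_training)) cat(",", z$n_training, "training samples")
    if (!is.null(z$n_irrigated)) cat(",", z$n_irrigated, "irrigated")
    cat("\n")
    if (!is.null(z$note)) cat("    note:", z$note, "\n")
    for (s in names(z$class_stats)) {
      st <- z$class_stats[[s]]
      cl <- z$classes[[s]]
      cat(sprintf(
        "    class %s (%s): n=%d, imclass [%s], mclass %.4f, mp %.4f, MVCI %.4f, irclass %.4f, theta %.4f, irrigated %d\n",
        s, cl$crop, cl$n_pixels,
        paste(sprintf("%.3f", st$ndvi_imclass), collapse = ", "),
        st$ndvi_mclass, st$ndvi_mp, st$mvci, st$ndvi_irclass,
        cl$theta, cl$n_irrigated))
    }
  }
  if (!is.null(x$n_irrigated)) cat("  total irrigated pixels:", x$n_irrigated, "\n")
  invisible(x)
}
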