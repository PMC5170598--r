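#' Spectral Correlation Mapper similarity
#'
#' Pearson-form similarity between a pixel's temporal NDVI profile and a
#' reference (end-member) profile: both vectors are centered on their means
#' and normalised, and the inner product is returned.  The score lies in
#' `[-1, 1]`; unlike the angular SAM measure it distinguishes negative from
#' positive correlation, which is what lets the classifier reject inverted
#' profiles.  Positive affine transforms leave the score at 1
#' (`scm_score(x, a*x + b) == 1` for `a > 0`).
#'
#' @param x,r numeric vectors of equal length `T >= 2`, neither constant.
#' @return similarity in `[-1, 1]`.
#' @seealso [sam_angle()] for the uncentered angular measure.
#' @export
scm_score <- function(x, r) {
  stopifnot(is.numeric(x), is.numeric(r), length(x) == length(r),
            length(x) >= 2L)
  if (anyNA(x) || anyNA(r)) stop("profiles must be free of NA", call. = FALSE)
  xc <- x - mean(x)
  rc <- r - mean(r)
  nx <- sqrt(sum(xc^2))
  nr <- sqrt(sum(rc^2))
  if (nx == 0 || nr == 0) {
    stop("SCM score undefined for a constant profile", call. = FALSE)
  }
  min(1, max(-1, sum(xc * rc) / (nx * nr)))
}

#' Spectral Angle Mapper angle
#'
#' The uncentered angular distance SCM modifies: the arc cosine of the
#' normalised inner product of the two raw vectors, in radians in `[0, pi]`.
#' Because no centering occurs, uniform positive scalings give angle 0 and
#' anti-correlated shapes are not singled out; kept for comparison with the
#' correlation mapper.
#'
#' @param x,r numeric nonzero vectors of equal length.
#' @return angle in radians.
#' @export
sam_angle <- function(x, r) {
  stopifnot(is.numeric(x), is.numeric(r), length(x) == length(r),
            length(x) >= 1L)
  if (anyNA(x) || anyNA(r)) stop("profiles must be free of NA", call. = FALSE)
  nx <- sqrt(sum(x^2))
  nr <- sqrt(sum(r^2))
  if (nx == 0 || nr == 0) {
    stop("SAM angle undefined for a zero vector", call. = FALSE)
  }
  acos(min(1, max(-1, sum(x * r) / (nx * nr))))
}

#' Build end-member signatures from training samples
#'
#' Each crop's reference temporal profile is the composite-wise mean of its
#' member training profiles.  Crops with fewer than `min_members` samples are
#' dropped (reported in the `"dropped"` attribute and via a message), as are
#' crops whose mean profile is constant and therefore unusable for
#' correlation matching.  Class ids are assigned in alphabetical crop order,
#' so they are deterministic.
#'
#' @param profiles numeric matrix, one training profile per row.
#' @param crops character vector of crop labels, parallel to rows.
#' @param min_members minimum members per crop (default 3).
#' @return list of signatures `list(class_id, crop_name, reference,
#'   n_members)`, ordered by `class_id`, with attribute `"dropped"`.
#' @export
build_signatures <- function(profiles, crops, min_members = 3L) {
  stopifnot(is.matrix(profiles), nrow(profiles) == length(crops))
  dropped <- data.frame(crop = character(), n_members = integer(),
                        reason = character(), stringsAsFactors = FALSE)
  sigs <- list()
  for (crop in sort(unique(crops))) {
    rows <- which(crops == crop)
    if (length(rows) < min_members) {
      dropped <- rbind(dropped, data.frame(
        crop = crop, n_members = length(rows), reason = "too few members",
        stringsAsFactors = FALSE))
      next
    }
    ref <- colMeans(profiles[rows, , drop = FALSE])
    if (diff(range(ref)) == 0) {
      dropped <- rbind(dropped, data.frame(
        crop = crop, n_members = length(rows), reason = "constant reference",
        stringsAsFactors = FALSE))
      next
    }
    sigs[[length(sigs) + 1L]] <- list(class_id = length(sigs) + 1L,
                                      crop_name = crop,
                                      reference = unname(ref),
                                      n_members = length(rows))
  }
  if (nrow(dropped)) {
    message("build_signatures: dropped ", nrow(dropped), " crop(s): ",
            paste(dropped$crop, collapse = ", "))
  }
  if (!length(sigs)) stop("no crop reaches the minimum number of members",
                          call. = FALSE)
  attr(sigs, "dropped") <- dropped
  sigs
}

#' Classify pixels to crop classes by SCM similarity
#'
#' Every masked pixel's profile is scored against every end-member signature;
#' the class with the highest correlation wins (ties toward the lowest class
#' id).  Pixels whose best score is not positive are never assigned (negative
#' correlation is excluded), and a configurable floor (default 0.5) rejects
#' weak matches; rejected pixels carry the reserved code 0 inside the mask.
#' Pixels with constant or `NA`-ridden profiles stay unclassified.
#'
#' @param ndvic an [ndvi_stack()].
#' @param signatures list from [build_signatures()].
#' @param mask optional `mask_layer`; default scores every pixel.
#' @param min_score minimum accepted best score (default 0.5).
#' @return object of class `crop_class_map`: `list(grid, codes, scores,
#'   legend)`; `codes` holds class ids, 0 = in-mask but unclassified, `NA` =
#'   outside the mask.
#' @export
classify_pixels <- function(ndvic, signatures, mask = NULL, min_score = 0.5) {
  stopifnot(inherits(ndvic, "ndvi_stack"), length(signatures) >= 1L)
  n_t <- dim(ndvic$values)[3]
  refs <- t(vapply(signatures, `[[`, numeric(n_t), "reference"))
  ids <- vapply(signatures, `[[`, integer(1), "class_id")
  o <- order(ids)
  refs <- refs[o, , drop = FALSE]
  ids <- ids[o]
  rc <- refs - rowMeans(refs)
  rn <- sqrt(rowSums(rc^2))
  if (any(rn == 0)) stop("constant signature reference", call. = FALSE)
  rc <- rc / rn

  grid <- ndvic$grid
  if (is.null(mask)) {
    include <- matrix(TRUE, grid$n_rows, grid$n_cols)
  } else {
    stop_if_grid_mismatch(grid, mask$grid, "ndvic and mask")
    include <- mask$include
  }
  codes <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  scores <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  px <- which(include, arr.ind = TRUE)
  if (nrow(px)) {
    prof <- t(apply(px, 1L, function(p) ndvic$values[p[1], p[2], ]))
    prof <- t(apply(prof, 1L, fill_gaps))
    valid <- !apply(prof, 1L, anyNA)
    pc <- prof - rowMeans(prof)
    pn <- sqrt(rowSums(pc^2))
    valid <- valid & pn > 0
    codes[px] <- 0L
    if (any(valid)) {
      sc <- (pc[valid, , drop = FALSE] / pn[valid]) %*% t(rc)
      best <- max.col(sc, ties.method = "first")
      best_sc <- sc[cbind(seq_len(nrow(sc)), best)]
      assigned <- best_sc > 0 & best_sc >= min_score
      cls <- ifelse(assigned, ids[best], 0L)
      codes[px[valid, , drop = FALSE]] <- cls
      scores[px[valid, , drop = FALSE]] <- best_sc
    }
  }
  legend <- stats::setNames(ids, vapply(signatures[o], `[[`, "", "crop_name"))
  structure(list(grid = grid, codes = codes, scores = scores,
                 legend = legend),
            class = "crop_class_map")
}

#' @export
print.crop_class_map <- function(x, ...) {
  tab <- table(factor(x$codes[!is.na(x$codes) & x$codes > 0L],
                      levels = x$legend, labels = names(x$legend)))
  cat("<crop_class_map>", sum(!is.na(x$codes)), "pixels in mask;",
      sum(x$codes == 0L, na.rm = TRUE), "unclassified\n")
  if (length(tab)) print(tab)
  invisible(x)
}

#' Export / import signatures as a delimited table
#'
#' One row per class: `class_id`, `crop_name`, `n_members`, then the `T`
#' reference values as columns `t0..t{T-1}`.
#'
#' @param signatures list from [build_signatures()].
#' @param path CSV path.
#' @return `path` (write) or the signature list (read).
#' @export
write_signatures <- function(signatures, path) {
  refs <- t(vapply(signatures, `[[`,
                   numeric(length(signatures[[1]]$reference)), "reference"))
  colnames(refs) <- paste0("t", seq_len(ncol(refs)) - 1L)
  df <- data.frame(class_id = vapply(signatures, `[[`, 1L, "class_id"),
                   crop_name = vapply(signatures, `[[`, "", "crop_name"),
                   n_members = vapply(signatures, `[[`, 1L, "n_members"),
                   refs, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  tcols <- grep("^t[0-9]+$", names(df))
  lapply(seq_len(nrow(df)), function(i) {
    list(class_id = as.integer(df$class_id[i]),
         crop_name = df$crop_name[i],
         reference = as.numeric(df[i, tcols]),
         n_members = as.integer(df$n_members[i]))
  })
}
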