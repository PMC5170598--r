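# Shared fixture builders: everything is generated in code at test time.

fixture_grid <- function(n = 4L, ps = 250) grid_spec(n, n, pixel_size = ps)

# single-hump NDVI profile with known emergence/senescence composites
hump_profile <- function(n_t = 23L, on = 2L, off = 9L, peak = 0.6,
                         base = 0.15) {
  x <- rep(base, n_t)
  idx <- (on + 1L):(off + 1L)                 # 0-based -> R
  w <- seq_along(idx)
  x[idx] <- base + (peak - base) * sin(pi * (w - 0.5) / length(w))
  x
}

# small fixture lookup used across phenology tests
fixture_lookup <- function() {
  data.frame(zone_id = 1L,
             crop_name = c("Rice", "Wheat"),
             season = c("Kharif", "Rabi"),
             height_min = c(55, 40), height_max = c(100, 100),
             duration_min = c(3, 3), duration_max = c(12, 12),
             priority = c(1L, 2L), stringsAsFactors = FALSE)
}

# truth-recovery rates of a pipeline result on a scene bundle, evaluated
# over the masked agricultural pixels
pipeline_accuracy <- function(bundle, result) {
  mask <- agricultural_mask(bundle$lulc, bundle$ag_codes, bundle$slope)
  tr <- bundle$truth
  inc <- mask$include[cbind(tr$row, tr$col)]
  pred <- result$irrigation$labels[cbind(tr$row, tr$col)]
  irr_acc <- mean((pred[inc] == 1L) == tr$irrigated[inc])
  leg <- result$crops$legend
  pcode <- result$crops$codes[cbind(tr$row, tr$col)]
  pcrop <- names(leg)[match(pcode, leg)]
  sel <- inc & tr$sown
  crop_acc <- mean(!is.na(pcrop[sel]) & pcrop[sel] == tr$crop[sel])
  list(irrigation = irr_acc, crop = crop_acc)
}

# brute-force SCM classification oracle: double loop over pixels and
# signatures, independent of the vectorised implementation
oracle_classify <- function(ndvic, signatures, min_score = 0.5) {
  g <- ndvic$grid
  codes <- matrix(NA_integer_, g$n_rows, g$n_cols)
  for (r in seq_len(g$n_rows)) {
    for (c in seq_len(g$n_cols)) {
      prof <- ndvic$values[r, c, ]
      if (anyNA(prof) || stats::sd(prof) == 0) { codes[r, c] <- 0L; next }
      best_id <- 0L
      best_sc <- -Inf
      for (s in signatures) {
        sc <- stats::cor(prof, s$reference)
        if (sc > best_sc + 1e-15) { best_sc <- sc; best_id <- s$class_id }
      }
      codes[r, c] <- if (best_sc > 0 && best_sc >= min_score) best_id else 0L
    }
  }
  codes
}
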