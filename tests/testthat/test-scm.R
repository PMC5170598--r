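test_that("SCM score obeys the Pearson affine laws and hand values", {
  expect_equal(scm_score(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(scm_score(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(scm_score(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84))
  expect_equal(scm_score(c(1, 2, 3), c(1, 2, 4)), 0.981981, tolerance = 1e-6)

  # affine law on generated vectors, symmetry, and cor() as cross-check
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(23)
    a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    b <- rnorm(1)
    expect_equal(scm_score(x, a * x + b), sign(a))
    y <- rnorm(23)
    expect_equal(scm_score(x, y), scm_score(y, x))
    expect_equal(scm_score(x, y), stats::cor(x, y))
  }
  expect_error(scm_score(rep(1, 5), 1:5), "constant")
})

test_that("SAM angle is the uncentered angular distance", {
  expect_equal(sam_angle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sam_angle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(sam_angle(c(1, 2, 3), c(1, 2, 4)), acos(17 / sqrt(294)))
  expect_equal(sam_angle(c(1, 2, 3), c(1, 2, 4)), 0.1308, tolerance = 1e-3)
  # scale-blind up to acos rounding near 1
  expect_equal(sam_angle(c(1, 2, 3), 3.7 * c(1, 2, 3)), 0, tolerance = 1e-6)
  expect_error(sam_angle(c(0, 0), c(1, 1)), "zero vector")
})

test_that("signatures are member means; small crops are dropped with a report", {
  profs <- rbind(c(0.2, 0.4), c(0.4, 0.6),
                 matrix(rep(c(0.1, 0.9), 3), 3, byrow = TRUE),
                 c(0.5, 0.5))
  crops <- c("A", "A", "B", "B", "B", "C")
  expect_message(sigs <- build_signatures(profs, crops, min_members = 2L),
                 "dropped")
  expect_length(sigs, 2L)
  expect_equal(sigs[[1]]$reference, c(0.3, 0.5))      # mean of A members
  expect_equal(sigs[[2]]$reference, c(0.1, 0.9))      # identical members
  expect_identical(attr(sigs, "dropped")$crop, "C")

  expect_error(suppressMessages(build_signatures(profs[6, , drop = FALSE],
                                                 "C", 3L)), "minimum")
})

test_that("pixel classification matches the brute-force oracle exactly", {
  set.seed(4)
  n_t <- 23L
  sig_a <- hump_profile(n_t, 2L, 9L, peak = 0.7)
  sig_b <- hump_profile(n_t, 12L, 18L, peak = 0.7)
  sigs <- list(list(class_id = 1L, crop_name = "A", reference = sig_a,
                    n_members = 3L),
               list(class_id = 2L, crop_name = "B", reference = sig_b,
                    n_members = 3L))
  g <- grid_spec(8, 8)
  vals <- array(NA_real_, c(8, 8, n_t))
  for (r in 1:8) for (c in 1:8) {
    base <- if ((r + c) %% 2 == 0) sig_a else sig_b
    vals[r, c, ] <- pmin(pmax(base * runif(1, 0.5, 1.4) +
                                rnorm(n_t, sd = 0.05), -1), 1)
  }
  st <- ndvi_stack(g, vals, seq(as.Date("2000-06-05"), by = 16,
                                length.out = n_t), "2000-01")
  cmap <- classify_pixels(st, sigs, min_score = 0.5)
  expect_identical(cmap$codes, oracle_classify(st, sigs, 0.5))
  expect_true(all(cmap$scores >= -1 & cmap$scores <= 1, na.rm = TRUE))
})

test_that("classification handles exact matches, anti-correlation and ties", {
  n_t <- 23L
  sig <- hump_profile(n_t, 2L, 9L, peak = 0.7)
  sigs <- list(list(class_id = 1L, crop_name = "A", reference = sig,
                    n_members = 3L))
  g <- grid_spec(1, 3)
  vals <- array(NA_real_, c(1, 3, n_t))
  vals[1, 1, ] <- sig                              # exact match
  vals[1, 2, ] <- max(sig) + min(sig) - sig        # anti-correlated
  vals[1, 3, ] <- rep(0.3, n_t)                    # constant
  st <- ndvi_stack(g, vals, seq(as.Date("2000-06-05"), by = 16,
                                length.out = n_t), "2000-01")
  cmap <- classify_pixels(st, sigs)
  expect_identical(cmap$codes[1, 1], 1L)
  expect_equal(cmap$scores[1, 1], 1)
  expect_identical(cmap$codes[1, 2], 0L)           # negative correlation
  expect_identical(cmap$codes[1, 3], 0L)           # undefined score

  # tie between identical signatures resolves to the lowest class id
  twin <- list(list(class_id = 1L, crop_name = "A", reference = sig,
                    n_members = 3L),
               list(class_id = 2L, crop_name = "B", reference = sig,
                    n_members = 3L))
  cmap2 <- classify_pixels(st, twin)
  expect_identical(cmap2$codes[1, 1], 1L)
})

test_that("pixels generated from the signatures classify back perfectly", {
  cfg <- scene_config(seed = 5, noise_sd = 0, frac_nonagricultural = 0,
                      frac_steep = 0)
  b <- generate_scene(cfg)
  mask <- agricultural_mask(b$lulc, b$ag_codes, b$slope)
  lat <- select_training_pixels(mask)
  tr <- build_training_samples(b$ndvi, lat, b$lookup, 1L)
  sigs <- build_signatures(tr$profiles, tr$samples$crop)
  cmap <- classify_pixels(b$ndvi, sigs, mask)
  leg <- cmap$legend
  pred <- names(leg)[match(cmap$codes[cbind(b$truth$row, b$truth$col)], leg)]
  sel <- b$truth$sown
  expect_identical(mean(pred[sel] == b$truth$crop[sel]), 1)
})

test_that("signature tables round-trip through CSV", {
  sigs <- list(list(class_id = 1L, crop_name = "Rice",
                    reference = hump_profile(23L), n_members = 5L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_signatures(sigs, f)
  back <- read_signatures(f)
  expect_equal(back[[1]]$reference, sigs[[1]]$reference)
  expect_identical(back[[1]]$crop_name, "Rice")
})
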