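test_that("spectral angle mapper matches its analytic anchors", {
  v <- rnorm(50) + 2
  expect_equal(sam(v, v), 0)
  expect_equal(sam(c(1, 0), c(0, 1)), 90)
  expect_equal(sam(c(1, 0), c(1, 1)), 45, tolerance = 1e-12)
  # positive-scale invariance and symmetry
  x <- rnorm(80); y <- rnorm(80)
  expect_equal(sam(x, 7.3 * y), sam(x, y), tolerance = 1e-9)
  expect_equal(sam(x, y), sam(y, x))
  # anti-parallel vectors reach 180 degrees via clipping, never NaN
  expect_equal(sam(x, -x), 180)
  expect_error(sam(x, rep(0, 80)), class = "raman_degenerate_error")
  expect_error(sam(x, y[1:10]), class = "raman_structural_error")
})

test_that("mean_spectrum reports bin-wise means and population variances", {
  shifts <- seq(800, 1800, by = 5)
  r <- snv(rnorm(length(shifts)))
  ds <- make_snv_set(rbind(r, r) * 1, tissue = rep("st_bone", 2),
                     head_id = 1:2, shifts = shifts)
  ms <- mean_spectrum(ds, "st_bone")
  expect_equal(ms$variance, rep(0, length(shifts)))
  expect_equal(ms$mean, as.numeric(ds$spectra[1, ]))

  ds2 <- make_snv_set(rbind(r, -r), tissue = rep("st_bone", 2),
                      head_id = 1:2, shifts = shifts)
  expect_equal(mean_spectrum(ds2, "st_bone")$mean, rep(0, length(shifts)),
               tolerance = 1e-12)
  # population (1/N) convention
  expect_equal(mean_spectrum(ds2, "st_bone")$variance,
               as.numeric(ds2$spectra[1, ])^2, tolerance = 1e-9)
  expect_error(mean_spectrum(ds, "st_dura"),
               class = "raman_insufficient_data_error")
})

test_that("synthetic class means concentrate around the expected processed profile", {
  cfg <- generator_config(seed = 5, n_heads = 2, records_per_tissue_per_head = 10,
                          head_effect_sd = 0, gland_prep_methods = FALSE)
  profs <- default_profiles()
  ds <- preprocess_dataset(generate_raw(cfg, profs["st_bone"]))
  ms <- mean_spectrum(ds, "st_bone")
  # an independent replication estimates the same expected processed profile:
  # the class mean concentrates on it as records accumulate
  cfg2 <- generator_config(seed = 105, n_heads = 2,
                           records_per_tissue_per_head = 10,
                           head_effect_sd = 0, gland_prep_methods = FALSE)
  ds2 <- preprocess_dataset(generate_raw(cfg2, profs["st_bone"]))
  ms2 <- mean_spectrum(ds2, "st_bone")
  tol <- 3 * sqrt(ms$variance / ms$n + ms2$variance / ms2$n) + 0.02
  expect_gt(mean(abs(ms$mean - ms2$mean) <= tol), 0.99)  # per-bin 3-sigma band
  # global agreement at the scale its own sampling variability predicts
  pred_rms <- sqrt(mean(ms$variance / ms$n + ms2$variance / ms2$n))
  expect_lt(sqrt(mean((ms$mean - ms2$mean)^2)), 1.5 * pred_rms)
  # and its shape follows the generator's noise-free processed profile
  nf <- generate_raw(noise_free_config(n_heads = 1,
                                       records_per_tissue_per_head = 1,
                                       gland_prep_methods = FALSE),
                     default_profiles(noise_scale = 0)["st_bone"])
  oracle <- preprocess(nf$acquisitions[[1]])$intensities
  expect_lt(sam(ms$mean, oracle), 10)
})

test_that("pairwise SAM is symmetric, zero-diagonal and scale-blind", {
  shifts <- seq(800, 1800, by = 5)
  r1 <- rnorm(length(shifts)); r2 <- rnorm(length(shifts))
  rows <- rbind(r1, r1 + rnorm(length(shifts), sd = 1e-8),
                3 * r1, 3 * r1 + rnorm(length(shifts), sd = 1e-8),
                r2, r2 + rnorm(length(shifts), sd = 1e-8))
  ds <- make_snv_set(rows,
                     tissue = rep(c("st_bone", "st_dura", "white_matter"), each = 2),
                     head_id = rep(1:2, 3), shifts = shifts)
  sm <- pairwise_sam(ds)
  expect_equal(diag(sm$angles), rep(0, 3), ignore_attr = TRUE)
  expect_equal(sm$angles, t(sm$angles))
  # SNV maps a positive multiple onto the identical fingerprint: angle ~ 0
  expect_lt(sm$angles["st_bone", "st_dura"], 1e-3)
  expect_gt(sm$angles["st_bone", "white_matter"], 10)
  expect_equal(sm$mean_offdiag, mean(sm$angles[upper.tri(sm$angles)]))

  only1 <- subset_records(ds, ds$meta$tissue == "st_bone")
  expect_error(pairwise_sam(only1), class = "raman_insufficient_data_error")
})

test_that("within/between SAM distributions behave at both noise extremes", {
  # noise-free generator: within-class angles are all below between-class ones
  cfg <- noise_free_config(n_heads = 2, records_per_tissue_per_head = 2,
                           n_pixels = 401, gland_prep_methods = FALSE)
  ds <- preprocess_dataset(generate_raw(cfg, default_profiles(noise_scale = 0)[
    c("st_bone", "pituitary_gland", "white_matter")]))
  wb <- within_between_sam(ds)
  expect_lt(max(wb$within$angle), min(wb$between$angle))

  # a high-noise generator reproduces the within/between overlap limitation
  cfg2 <- tiny_config(seed = 3, n_pixels = 401)
  ds2 <- preprocess_dataset(generate_raw(cfg2, default_profiles(noise_scale = 8)[
    c("st_bone", "st_dura", "pituitary_gland")]))
  wb2 <- within_between_sam(ds2)
  expect_gt(wb2$overlap_fraction, 0)

  # two records of different tissues: empty within, a single between angle
  shifts <- seq(800, 1800, by = 5)
  ds3 <- make_snv_set(matrix(rnorm(2 * length(shifts)), 2),
                      tissue = c("st_bone", "st_dura"), head_id = c(1, 1),
                      shifts = shifts)
  wb3 <- within_between_sam(ds3)
  expect_equal(nrow(wb3$within), 0)
  expect_equal(nrow(wb3$between), 1)
})

test_that("preparation-method comparison handles identical and distinct methods", {
  shifts <- seq(800, 1800, by = 5)
  r <- rnorm(length(shifts))
  rows <- do.call(rbind, replicate(6, r, simplify = FALSE))
  ds <- make_snv_set(rows, tissue = rep("pituitary_gland", 6),
                     head_id = rep(1, 6),
                     prep_method = rep(RAMAN_PREP_METHODS, each = 2),
                     shifts = shifts)
  pc <- prep_method_comparison(ds)
  pooled_v <- pc$variance[pc$variance$head == "pooled", ]
  expect_equal(pooled_v$total_variance, rep(0, 3))
  pooled_s <- pc$sam[pc$sam$head == "pooled", ]
  expect_equal(pooled_s$angle, rep(0, 3), tolerance = 1e-6)

  non_gland <- make_snv_set(rows, tissue = rep("st_bone", 6),
                            head_id = rep(1:3, 2), shifts = shifts)
  expect_error(prep_method_comparison(non_gland),
               class = "raman_insufficient_data_error")
})
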