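test_that("dark subtraction is elementwise and validates lengths", {
  expect_equal(subtract_dark(matrix(c(100, 110), 1), c(10, 10)),
               matrix(c(90, 100), 1))
  f <- matrix(5, 3, 4)
  expect_equal(subtract_dark(f, rep(5, 4)), matrix(0, 3, 4))
  expect_equal(subtract_dark(f, rep(0, 4)), f)
  expect_error(subtract_dark(f, rep(0, 3)), class = "raman_structural_error")
})

test_that("cosmic-ray removal replaces spikes and only spikes", {
  set.seed(1)
  base <- matrix(rep(runif(200, 100, 200), each = 10), 10, 200)
  frames <- base
  frames[4, 57] <- frames[4, 57] + 1e4
  out <- remove_cosmic_rays(frames, threshold = 8)
  expect_equal(out[4, 57], base[4, 57])
  expect_equal(out[-4, ], base[-4, ])
  expect_equal(max(abs(out[, -57] - base[, -57])), 0)

  # a spike present in every frame at the same pixel survives (median follows it)
  stuck <- base; stuck[, 31] <- stuck[, 31] + 1e4
  expect_equal(remove_cosmic_rays(stuck, 8)[, 31], stuck[, 31])
})

test_that("spike-free noisy frames are almost never altered", {
  set.seed(42)
  altered <- 0L; total <- 0L
  for (i in 1:100) {
    frames <- matrix(rnorm(10 * 500, mean = 1000, sd = 30), 10, 500)
    out <- remove_cosmic_rays(frames, threshold = 8)
    altered <- altered + sum(out != frames)
    total <- total + length(frames)
  }
  expect_lt(altered / total, 0.001)
})

test_that("axis calibration recovers linear and quadratic truths", {
  # consistent linear data are reproduced to numerical precision
  calib <- default_calibration(401, c(400, 2000))
  ax <- calibrate_axis(calib, 401, degree = 2)
  expect_lt(max(abs(ax$shifts - seq(400, 2000, length.out = 401))), 1e-6)

  # a quadratic pixel -> shift truth is recovered from 5 exact peaks
  truthfun <- function(p) 380 + 3.9 * p + 0.0004 * p^2
  px <- c(20, 90, 160, 260, 380)
  calib2 <- calibration_set(px, truthfun(px), rep(1, 401))
  ax2 <- calibrate_axis(calib2, 401, degree = 2)
  expect_lt(max(abs(ax2$shifts - truthfun(1:401))), 1e-6)

  # underdetermined fits and non-monotone mappings are calibration errors
  expect_error(calibrate_axis(calibration_set(c(10, 50), c(500, 700), rep(1, 10)),
                              401, degree = 2),
               class = "raman_calibration_error")
  downup <- function(p) 2000 - 3 * p + 0.004 * p^2   # decreasing below p = 375
  px <- c(20, 100, 200, 300, 380)
  bad <- calibration_set(px, downup(px), rep(1, 401))
  expect_error(calibrate_axis(bad, 401, degree = 2),
               class = "raman_calibration_error")
})

test_that("response correction divides by the mean-normalized response", {
  calib_flat <- calibration_set(c(1, 2, 3), c(500, 700, 900), rep(2, 100))
  x <- rnorm(100) + 10
  # constant response (any level) is an exact identity
  expect_equal(correct_response(x, calib_flat), x)
  # a linear response applied to a flat spectrum gives the reciprocal ramp
  resp <- seq(2, 1, length.out = 100)
  calib_ramp <- calibration_set(c(1, 2, 3), c(500, 700, 900), resp)
  flat <- rep(5, 100)
  expect_equal(correct_response(flat, calib_ramp), 5 * mean(resp) / resp)
  expect_error(correct_response(x, calibration_set(1:3, 1:3, rep(1, 50))),
               class = "raman_structural_error")
})

test_that("bubblefill returns the input for straight lines and splits signal from background", {
  shifts <- seq(400, 2000, by = 1)
  line <- 5 + 0.3 * shifts
  bb <- bubblefill_baseline(line, shifts, 50)
  expect_lt(max(abs(bb$raman)), 1e-9)
  expect_equal(bb$baseline, line)

  u <- (shifts - 400) / 1600
  bl_true <- 1500 + 600 * u + 400 * u^2
  pk <- 800 * pv_peak(shifts, 950, 15) + 1000 * pv_peak(shifts, 1300, 15) +
    900 * pv_peak(shifts, 1650, 15)
  bb2 <- bubblefill_baseline(bl_true + pk, shifts, 50)
  expect_true(all(bb2$baseline <= bl_true + pk + 1e-9))
  expect_true(all(bb2$raman >= 0))

  # scale equivariance: baseline(c * s) = c * baseline(s)
  bb3 <- bubblefill_baseline(3 * (bl_true + pk), shifts, 50)
  expect_equal(bb3$baseline, 3 * bb2$baseline, tolerance = 1e-9)

  # near-idempotence on its own raman output (arc scallops stay below 1%)
  bb4 <- bubblefill_baseline(bb2$raman, shifts, 50)
  rel <- sqrt(mean((bb4$raman - bb2$raman)^2)) / sqrt(mean(bb2$raman^2))
  expect_lt(rel, 0.01)
})

test_that("Savitzky-Golay smoothing honours its analytic properties", {
  x <- rnorm(301)
  expect_identical(smooth_sg(x, 3, 1), x)              # window 1 is a no-op
  expect_error(smooth_sg(x, 3, 4), class = "raman_param_error")
  expect_error(smooth_sg(x, 3, 3), class = "raman_param_error")

  t <- seq(-1, 1, length.out = 301)
  cubic <- 2 - t + 0.5 * t^2 + 3 * t^3
  expect_lt(max(abs(smooth_sg(cubic, 3, 11) - cubic)), 1e-9)

  set.seed(3)
  noise <- rnorm(2000)
  expect_lt(var(smooth_sg(noise, 3, 11)), var(noise))
})

test_that("truncation keeps exactly the window and errors when empty", {
  shifts <- seq(400, 2000, by = 1)
  x <- rnorm(length(shifts))
  tr <- truncate_spectrum(x, shifts, 800, 1800)
  expect_length(tr$intensities, 1001)
  expect_equal(range(tr$shifts), c(800, 1800))
  one <- truncate_spectrum(x, shifts, 1004, 1004)
  expect_length(one$intensities, 1)
  expect_error(truncate_spectrum(x, shifts, 2100, 2200),
               class = "raman_range_error")
})

test_that("snv matches hand-computed values and rejects constants", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  x <- snv(rnorm(100) * 7 + 3)
  expect_lt(abs(mean(x)), 1e-12)
  expect_lt(abs(sqrt(mean((x - mean(x))^2)) - 1), 1e-12)
  expect_error(snv(rep(4, 10)), class = "raman_degenerate_error")
})

test_that("parameter validation rejects bad windows and permuted stage orders", {
  expect_error(preprocess_params(sg_window = 2), class = "raman_param_error")
  expect_error(preprocess_params(bubble_min_width = 0), class = "raman_param_error")
  expect_error(preprocess_params(truncate_lo = 1800, truncate_hi = 800),
               class = "raman_param_error")
  expect_error(preprocess_params(stage_order = c("snv", "dark")),
               class = "raman_param_error")
  expect_silent(preprocess_params(stage_order = preprocess_params()$stage_order))
})

test_that("the full chain recovers the SNV of the noise-free truth", {
  cfg <- noise_free_config(n_heads = 1, records_per_tissue_per_head = 1,
                           gland_prep_methods = FALSE)
  profs <- default_profiles(noise_scale = 0)
  for (tis in c("st_bone", "pituitary_gland")) {
    raw <- generate_raw(cfg, profs[tis])
    p <- preprocess(raw$acquisitions[[1]])
    es <- expected_signal(profs[[tis]], cfg, profs)
    idx <- match(round(p$axis$shifts), round(es$shifts))
    oracle <- snv(es$peaks[idx])
    # error normalized by the fingerprint's dynamic range; the 4% bound covers
    # the baseline-envelope bias documented for the bubble estimator
    nrmse <- sqrt(mean((p$intensities - oracle)^2)) / diff(range(oracle))
    expect_lt(nrmse, 0.04)
    expect_true(is.na(p$qf))
  }
})

test_that("injected cosmic rays barely perturb the processed output", {
  cfg <- tiny_config(seed = 8, cosmic_ray_rate = 0, n_pixels = 1601)
  raw <- generate_raw(cfg, default_profiles()["st_bone"])
  a <- raw$acquisitions[[1]]
  spiked <- a
  set.seed(99)
  at <- cbind(sample(nrow(a$frames), 3, replace = TRUE),
              sample(ncol(a$frames), 3))
  spiked$frames[at] <- pmin(spiked$frames[at] + runif(3, 5000, 12000),
                            a$saturation)
  p0 <- preprocess(a)
  p1 <- preprocess(spiked)
  nrmse <- sqrt(mean((p1$intensities - p0$intensities)^2)) /
    diff(range(p0$intensities))
  expect_lt(nrmse, 0.005)
})

test_that("the chain is invariant to accumulation order and bit-stable", {
  raw <- generate_raw(tiny_config(seed = 12), default_profiles()["nasal_mucosa"])
  a <- raw$acquisitions[[1]]
  p1 <- preprocess(a)
  a2 <- a; a2$frames <- a$frames[sample(nrow(a$frames)), ]
  p2 <- preprocess(a2)
  expect_identical(p1$intensities, p2$intensities)
  p3 <- preprocess(a)
  expect_identical(p1$intensities, p3$intensities)
})

test_that("stage failures are tagged with the failing stage", {
  raw <- generate_raw(tiny_config(seed = 2, n_heads = 2),
                      default_profiles()["st_bone"])
  a <- raw$acquisitions[[1]]
  downup <- function(p) 2000 - 3 * p + 0.004 * p^2
  px <- c(20, 100, 200, 300, 380)
  bad_calib <- calibration_set(px, downup(px), rep(1, a$axis_pixels))
  err <- tryCatch(preprocess(a, bad_calib), error = identity)
  expect_s3_class(err, "raman_calibration_error")
  expect_match(conditionMessage(err), "stage calibrate")
})
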