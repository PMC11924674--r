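test_that("head-disjoint splitting enumerates subsets and never splits a head", {
  meta <- data.frame(head_id = rep(1:6, each = 10))
  sp <- split_by_head(meta, seed = 1)
  expect_length(sp$test_heads, 2)
  expect_equal(sp$test_fraction, 1 / 3, tolerance = 1e-9)
  expect_length(intersect(sp$train_heads, sp$test_heads), 0)
  expect_setequal(c(sp$train_heads, sp$test_heads), 1:6)
  expect_true(sp$feasible)

  # 90/10 record split over two heads: no feasible subset, plan is flagged
  meta2 <- data.frame(head_id = rep(c(1, 2), times = c(90, 10)))
  expect_warning(sp2 <- split_by_head(meta2, seed = 1), "no head subset")
  expect_false(sp2$feasible)
  expect_length(intersect(sp2$train_heads, sp2$test_heads), 0)

  expect_error(split_by_head(data.frame(head_id = rep(1, 5))),
               class = "raman_insufficient_data_error")
})

test_that("peak masks cover +/- halfwidth around in-range centers", {
  shifts <- seq(800, 1800, by = 1)
  idx <- peak_mask(shifts, 961, 25)
  expect_length(idx, 51)
  expect_equal(range(shifts[idx]), c(936, 986))
  expect_equal(shifts[peak_mask(shifts, c(961, 1004), 0)], c(961, 1004))
  expect_message(peak_mask(shifts, c(961, 2100), 25), "outside the axis")
  expect_error(peak_mask(shifts, 3000, 25), class = "raman_param_error")
  expect_error(peak_mask(shifts, numeric(0), 25), class = "raman_param_error")
})

test_that("L1 selection recovers a planted discriminative band", {
  hits <- 0L
  for (seed in 1:20) {
    pb <- planted_band_set(n_per_class = 15, center = 1300, amp = 3, seed = seed)
    mask <- peak_mask(pb$shifts, c(1004, 1128, 1300, 1650), 25)
    sel <- select_features_l1(pb$x, pb$y, pb$shifts, mask, seed = seed)
    expect_lt(length(sel$bins), 20)
    expect_gte(length(sel$bins), 1)
    hits <- hits + (mean(abs(sel$bins - 1300) <= 25) >= 0.8)
  }
  expect_gte(hits, 16L)  # selected bins concentrate at the planted band
})

test_that("L1 selection flags uninformative problems at chance accuracy", {
  set.seed(31)
  x <- matrix(rnorm(60 * 200), 60)
  y <- rep(c("a", "b"), each = 30)
  shifts <- seq(800, 1800, length.out = 200)
  sel <- select_features_l1(x, y, shifts, seq_len(200), seed = 31)
  expect_true(sel$uninformative)
  expect_lt(sel$cv_accuracy, 0.7)
  expect_lt(length(sel$bins), 20)
})

test_that("the L2 stage is exact on separable data and honest under permutation", {
  pb <- planted_band_set(n_per_class = 20, amp = 8, sd = 0.3, seed = 5)
  i1300 <- which(abs(pb$shifts - 1300) <= 10)
  l2 <- fit_l2(pb$x[, i1300], factor(pb$y), seed = 5)
  expect_equal(l2$cv_accuracy, 1)
  expect_equal(sum(diag(l2$cv_confusion)), length(pb$y))

  # same seed, same data -> identical weights; different seed may differ
  l2b <- fit_l2(pb$x[, i1300], factor(pb$y), seed = 5)
  expect_identical(l2$models[[1]]$w, l2b$models[[1]]$w)
  expect_identical(l2$cost, l2b$cost)

  # label permutation drives CV accuracy to chance within Monte-Carlo error
  set.seed(17)
  accs <- replicate(8, {
    yp <- sample(pb$y)
    fit_l2(pb$x[, i1300], factor(yp), seed = 1)$cv_accuracy
  })
  n <- length(pb$y)
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / n) + 0.05)

  expect_error(fit_l2(pb$x[, i1300], factor(rep("a", nrow(pb$x)))),
               class = "raman_task_error")
})

test_that("validation confusion totals equal the training record count", {
  raw <- generate_raw(generator_config(seed = 3, n_heads = 6,
                                       records_per_tissue_per_head = 3,
                                       n_pixels = 801,
                                       gland_prep_methods = FALSE),
                      default_profiles()[c("pituitary_gland", "st_bone",
                                           "optic_chiasm", "st_dura")])
  ds <- gate_quality(preprocess_dataset(raw))$dataset
  m <- raman_svm(ds, "four_class", seed = 3)
  expect_equal(sum(m$cv$confusion), m$cv$n)
  expect_equal(as.numeric(rowSums(m$test$confusion)),
               as.numeric(table(factor(
                 ds$meta$tissue[ds$meta$head_id %in% m$split$test_heads],
                 levels = m$classes))))
  expect_lt(length(m$selected_bins), 20)
  expect_true(all(m$selected_idx %in% m$candidate_mask))
})

test_that("model evaluation certifies head-disjointness and flags leakage", {
  raw <- generate_raw(generator_config(seed = 4, n_heads = 6,
                                       records_per_tissue_per_head = 3,
                                       n_pixels = 801,
                                       gland_prep_methods = FALSE),
                      default_profiles()[c("pituitary_gland", "st_bone")])
  ds <- gate_quality(preprocess_dataset(raw))$dataset
  m <- raman_svm(ds, "gland_vs_st_bone", seed = 4)
  expect_length(intersect(m$split$train_heads, m$split$test_heads), 0)

  train_records <- subset_records(ds, ds$meta$head_id %in% m$split$train_heads)
  expect_error(evaluate_model(m, train_records), class = "raman_leakage_error")

  # a perfect test report has an identity-structured confusion and AUC 1
  if (m$test$accuracy == 1) {
    expect_true(all(m$test$confusion[row(m$test$confusion) != col(m$test$confusion)] == 0))
    expect_equal(m$test$auc, 1)
  }
  expect_true(all(m$test$per_class$sensitivity >= 0 &
                    m$test$per_class$sensitivity <= 1))

  # refitting with the same seed is deterministic end to end
  m2 <- raman_svm(ds, "gland_vs_st_bone", seed = 4)
  expect_identical(coef(m), coef(m2))
  expect_identical(m$selected_bins, m2$selected_bins)
})

test_that("predict dispatches on datasets, full matrices and selected-bin matrices", {
  raw <- generate_raw(generator_config(seed = 6, n_heads = 6,
                                       records_per_tissue_per_head = 3,
                                       n_pixels = 801,
                                       gland_prep_methods = FALSE),
                      default_profiles()[c("pituitary_gland", "st_bone")])
  ds <- gate_quality(preprocess_dataset(raw))$dataset
  m <- raman_svm(ds, "gland_vs_st_bone", seed = 6)
  p1 <- predict(m, ds)
  p2 <- predict(m, ds$spectra)
  p3 <- predict(m, ds$spectra[, m$selected_idx, drop = FALSE])
  expect_identical(p1, p2)
  expect_identical(p1, p3)
  expect_equal(mean(p1 == ds$meta$tissue), 1, tolerance = 0.1)
  sc <- predict(m, ds, type = "score")
  expect_type(sc, "double")
  expect_error(predict(m, ds$spectra[, 1:7]), class = "raman_structural_error")
})

test_that("the binary suite trains exactly the seven protocol models", {
  raw <- generate_raw(generator_config(seed = 2, n_heads = 5,
                                       records_per_tissue_per_head = 2,
                                       n_pixels = 801,
                                       gland_prep_methods = FALSE))
  ds <- gate_quality(preprocess_dataset(raw))$dataset
  suite <- run_model_I(ds, seed = 2)
  expect_length(suite, 7)
  expect_setequal(names(suite),
                  c(paste0("gland_vs_", c("st_bone", "st_dura", "optic_chiasm",
                                          "sphenoid_bone", "white_matter",
                                          "gray_matter")), "gland_vs_rest"))
  # no dedicated binary against the nasal tissues
  expect_false(any(grepl("nasal", names(suite))))
  for (f in suite) {
    expect_lt(length(f$selected_bins), 20)
    expect_length(intersect(f$split$train_heads, f$split$test_heads), 0)
    expect_false(is.null(f$test$auc))
  }
})

test_that("an in-situ four-class model transfers to other gland preparations", {
  raw <- generate_raw(generator_config(seed = 7, n_heads = 6,
                                       records_per_tissue_per_head = 4,
                                       n_pixels = 801),
                      default_profiles()[c("pituitary_gland", "st_bone",
                                           "optic_chiasm", "st_dura")])
  ds <- gate_quality(preprocess_dataset(raw))$dataset
  m <- run_model_II(ds, seed = 7)
  tr <- transfer_to_methods(m, ds)
  expect_setequal(names(tr$counts), c("ex_situ", "in_section"))
  expect_true(all(tr$gland_recall >= 0.9))
  expect_equal(as.numeric(tr$n),
               as.numeric(table(ds$meta$prep_method)[c("ex_situ", "in_section")]))

  bad <- ds
  bad$meta$tissue[bad$meta$prep_method == "ex_situ"][1] <- "st_bone"
  expect_error(transfer_to_methods(m, bad), class = "raman_task_error")

  only_insitu <- subset_records(ds, ds$meta$prep_method == "in_situ")
  expect_warning(expect_warning(transfer_to_methods(m, only_insitu)))
})
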