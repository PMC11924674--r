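parse_task <- function(task) {
  if (task == "four_class")
    return(list(kind = "four_class",
                tissues = c("pituitary_gland", "st_bone", "optic_chiasm", "st_dura")))
  if (task == "gland_vs_rest")
    return(list(kind = "gland_vs_rest", tissues = RAMAN_TISSUES))
  if (grepl("^gland_vs_", task)) {
    other <- sub("^gland_vs_", "", task)
    if (!other %in% RAMAN_TISSUES)
      abort_task(sprintf("unknown tissue in task '%s'", task))
    return(list(kind = "binary", tissues = c("pituitary_gland", other)))
  }
  abort_task(sprintf(
    "unknown task '%s' (use 'four_class', 'gland_vs_rest' or 'gland_vs_<tissue>')",
    task))
}

task_labels <- function(kind, tissue) {
  if (kind == "gland_vs_rest")
    ifelse(tissue == "pituitary_gland", "pituitary_gland", "other")
  else tissue
}

#' Fit a two-stage sparse linear SVM tissue classifier
#'
#' The modelling scheme used for probe-based tissue discrimination: records
#' are split into training and hold-out sets that never share a head
#' (subject), candidate features are restricted to bins near known Raman
#' bands, an L1-penalized linear classifier reduces them to fewer than
#' `max_features` bins, and an L2-regularized linear SVM (one-vs-rest for
#' multi-class tasks) is trained on the survivors. Both stages are tuned by
#' seeded, class-stratified fivefold cross-validation on the training heads
#' only; the hold-out heads are touched exactly once, by [evaluate_model()].
#'
#' Only `in_situ` records enter training and testing; gland spectra acquired
#' ex situ or in section are scored separately via [transfer_to_methods()].
#'
#' @param ds A processed, quality-gated [raman_set()].
#' @param task `"four_class"` (gland / sella bone / optic chiasm / sella
#'   dura), `"gland_vs_rest"`, or `"gland_vs_<tissue>"`.
#' @param seed Seed controlling the split tie-break and fold assignments.
#' @param split_fraction Hold-out record share, default `c(0.33, 0.40)`.
#' @param halfwidth Peak-region half-width in cm-1 (default 25).
#' @param max_features Sparsity bound (selected bins `< max_features`).
#' @param costs L2 cost grid.
#' @param lambda L1 penalty grid.
#' @param nfolds CV folds.
#' @param class_weights Inverse-frequency class weights (default off).
#' @param registry Band registry supplying candidate peak centers.
#' @return An object of class `raman_svm` with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods. Key fields: `selected_bins` (cm-1),
#'   `cv` (validation accuracy + aggregated confusion), `test` (the hold-out
#'   [evaluate_model()] report) and `split` (the head-disjoint plan).
#' @export
raman_svm <- function(ds, task = "four_class", seed = 1,
                      split_fraction = c(0.33, 0.40), halfwidth = 25,
                      max_features = 20, costs = 10^(-3:3),
                      lambda = 10^seq(3, -3, length.out = 25),
                      nfolds = 5, class_weights = FALSE,
                      registry = default_band_registry()) {
  stopifnot(inherits(ds, "raman_set"))
  spec <- parse_task(task)
  keep <- ds$meta$prep_method == "in_situ" & ds$meta$tissue %in% spec$tissues
  sub <- subset_records(ds, keep)
  missing <- setdiff(if (spec$kind == "binary") spec$tissues else
    intersect(spec$tissues, c("pituitary_gland", "st_bone", "optic_chiasm", "st_dura")),
    unique(sub$meta$tissue))
  if (spec$kind != "gland_vs_rest" && length(missing))
    abort_task(sprintf("task '%s' requires tissues missing from the data: %s",
                       task, paste(missing, collapse = ", ")))
  if (spec$kind == "gland_vs_rest" &&
      !all(c("pituitary_gland") %in% sub$meta$tissue))
    abort_task("gland_vs_rest requires pituitary gland records")

  split <- split_by_head(sub, split_fraction, seed)
  tr <- sub$meta$head_id %in% split$train_heads
  train <- subset_records(sub, tr)
  test <- subset_records(sub, !tr)

  y <- factor(task_labels(spec$kind, train$meta$tissue))
  if (spec$kind != "four_class")  # gland first so scores point at the gland
    y <- stats::relevel(y, "pituitary_gland")
  shifts <- sub$axis$shifts

  centers <- registry$center[rowSums(registry[, intersect(spec$tissues,
                                                          names(registry)),
                                              drop = FALSE] > 0) > 0]
  mask <- peak_mask(shifts, centers, halfwidth)
  l1 <- select_features_l1(train$spectra, y, shifts, mask,
                           max_features = max_features, lambda = lambda,
                           nfolds = nfolds, seed = seed)
  l2 <- fit_l2(train$spectra[, l1$idx, drop = FALSE], y, costs = costs,
               nfolds = nfolds, seed = seed, class_weights = class_weights)

  cls_means <- vapply(levels(y), function(cl)
    colMeans(train$spectra[y == cl, , drop = FALSE]), numeric(ncol(train$spectra)))

  obj <- structure(list(
    task = task, kind = spec$kind, classes = l2$classes,
    axis = sub$axis, candidate_mask = mask,
    selected_bins = l1$bins, selected_idx = l1$idx,
    l1 = l1, l2 = l2,
    cv = list(accuracy = l2$cv_accuracy, confusion = l2$cv_confusion,
              n = nrow(train$spectra)),
    split = split, seed = seed,
    train_class_means = cls_means,
    call = match.call()), class = "raman_svm")
  obj$test <- evaluate_model(obj, test)
  obj
}

score_newdata <- function(object, newdata) {
  if (inherits(newdata, "raman_set")) {
    if (length(newdata$axis$shifts) != length(object$axis$shifts) ||
        max(abs(newdata$axis$shifts - object$axis$shifts)) > 1e-6)
      abort_structural("newdata axis does not match the model axis")
    newdata$spectra[, object$selected_idx, drop = FALSE]
  } else {
    x <- as.matrix(newdata)
    if (ncol(x) == length(object$axis$shifts))
      x[, object$selected_idx, drop = FALSE]
    else if (ncol(x) == length(object$selected_idx)) x
    else abort_structural("newdata columns match neither the full axis nor the selected bins")
  }
}

#' Predict tissue classes or decision scores
#'
#' @param object A [raman_svm()] fit.
#' @param newdata A [raman_set()] on the model axis, a full-axis spectra
#'   matrix, or a matrix already restricted to the selected bins.
#' @param type `"class"` or `"score"` (signed distance to the hyperplane;
#'   one column per class for multi-class fits).
#' @param ... Unused.
#' @export
predict.raman_svm <- function(object, newdata, type = c("class", "score"), ...) {
  predict_l2(object$l2, score_newdata(object, newdata), match.arg(type))
}

#' @export
coef.raman_svm <- function(object, ...) {
  w <- vapply(object$l2$models, function(m) m$w,
              numeric(length(object$selected_idx)))
  w <- matrix(w, nrow = length(object$selected_idx))
  rownames(w) <- sprintf("%.1f", object$selected_bins)
  colnames(w) <- if (object$l2$binary) object$classes[1] else object$classes
  w
}

#' @export
print.raman_svm <- function(x, ...) {
  cat(sprintf("<raman_svm> task %s (%d classes)\n", x$task, length(x$classes)))
  cat(sprintf("  split: train heads {%s} | test heads {%s} (test fraction %.2f)\n",
              paste(x$split$train_heads, collapse = ","),
              paste(x$split$test_heads, collapse = ","),
              x$split$test_fraction))
  cat(sprintf("  features: %d bins (cm-1): %s\n", length(x$selected_bins),
              paste(sprintf("%.0f", x$selected_bins), collapse = ", ")))
  cat(sprintf("  validation accuracy %.3f (n = %d) | test accuracy %.3f (n = %d)\n",
              x$cv$accuracy, x$cv$n, x$test$accuracy, x$test$n))
  if (!is.null(x$test$auc)) cat(sprintf("  test ROC AUC %.3f\n", x$test$auc))
  invisible(x)
}

#' @export
summary.raman_svm <- function(object, ...) {
  print(object)
  cat("\nValidation confusion (aggregated over folds):\n")
  print(object$cv$confusion)
  cat("\nTest confusion:\n")
  print(object$test$confusion)
  cat("\nPer-class test metrics:\n")
  print(object$test$per_class, row.names = FALSE)
  invisible(object)
}

#' Plot class mean fingerprints with the selected bins highlighted
#'
#' @param x A [raman_svm()] fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.raman_svm <- function(x, ...) {
  shifts <- x$axis$shifts
  graphics::matplot(shifts, x$train_class_means, type = "l", lty = 1,
                    xlab = "Raman shift (cm-1)", ylab = "SNV intensity",
                    main = sprintf("Training class means: %s", x$task), ...)
  graphics::abline(v = x$selected_bins, col = grDevices::adjustcolor("steelblue", 0.35))
  graphics::legend("topleft", legend = colnames(x$train_class_means),
                   col = seq_len(ncol(x$train_class_means)), lty = 1, bty = "n")
  invisible(x)
}

#' Evaluate a fitted model on held-out records
#'
#' Verifies that the test records share no head with the training set (a
#' violation is a hard `raman_leakage_error`), then reports the confusion
#' matrix, accuracy, per-class sensitivity and specificity, and, for binary
#' tasks, the ROC curve of the signed decision score with its trapezoid-rule
#' AUC.
#'
#' @param object A [raman_svm()] fit.
#' @param test A [raman_set()] of held-out records.
#' @param check_heads Set `FALSE` only for scoring records that deliberately
#'   reuse training heads (see [transfer_to_methods()]).
#' @return An `evaluation_report`.
#' @export
evaluate_model <- function(object, test, check_heads = TRUE) {
  stopifnot(inherits(test, "raman_set"))
  if (check_heads) {
    overlap <- intersect(object$split$train_heads, unique(test$meta$head_id))
    if (length(overlap))
      abort_leakage(sprintf(
        "test records share head(s) %s with the training set",
        paste(overlap, collapse = ", ")))
  }
  truth <- factor(task_labels(object$kind, test$meta$tissue),
                  levels = object$classes)
  pred <- predict(object, test)
  conf <- table(truth = truth, predicted = pred)
  acc <- if (length(truth)) mean(pred == truth) else NA_real_
  out <- list(confusion = conf, accuracy = acc,
              per_class = confusion_stats(conf), n = length(truth),
              split = object$split)
  if (object$l2$binary && length(truth) && nlevels(droplevels(truth)) == 2) {
    sc <- predict(object, test, type = "score")
    roc <- pROC::roc(response = truth, predictor = sc,
                     levels = c(object$classes[2], object$classes[1]),
                     direction = "<", quiet = TRUE)
    out$auc <- as.numeric(pROC::auc(roc))
    crd <- pROC::coords(roc, x = "all", ret = c("threshold", "sensitivity",
                                                "specificity"))
    out$roc <- data.frame(threshold = crd$threshold,
                          sensitivity = crd$sensitivity,
                          specificity = crd$specificity)
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> accuracy %.3f on %d records%s\n",
              x$accuracy, x$n,
              if (!is.null(x$auc)) sprintf(", AUC %.3f", x$auc) else ""))
  print(x$confusion)
  invisible(x)
}

#' Binary model suite: gland vs each neighbour and gland vs rest
#'
#' Trains one two-class model per clinically relevant neighbour tissue
#' (sella bone, sella dura, optic chiasm, sphenoid bone, white and gray
#' matter) plus one gland-vs-everything model — seven models in total. No
#' dedicated binaries are built against the nasal septum or mucosa (too few
#' records in the acquisition protocol to hold out a robust test set),
#' though both contribute to the pooled "rest" class.
#'
#' @param ds A processed, quality-gated [raman_set()].
#' @param seed Base seed; each task is offset deterministically.
#' @param ... Passed to [raman_svm()].
#' @return A named list of `raman_svm` fits, class `raman_model_suite`.
#' @export
run_model_I <- function(ds, seed = 1, ...) {
  others <- c("st_bone", "st_dura", "optic_chiasm", "sphenoid_bone",
              "white_matter", "gray_matter")
  tasks <- c(paste0("gland_vs_", others), "gland_vs_rest")
  fits <- lapply(seq_along(tasks), function(i)
    raman_svm(ds, tasks[i], seed = seed + i - 1, ...))
  names(fits) <- tasks
  structure(fits, class = "raman_model_suite")
}

#' @export
print.raman_model_suite <- function(x, ...) {
  tab <- do.call(rbind, lapply(names(x), function(nm) {
    f <- x[[nm]]
    data.frame(task = nm, n_features = length(f$selected_bins),
               validation_accuracy = round(f$cv$accuracy, 3),
               test_accuracy = round(f$test$accuracy, 3),
               test_auc = if (!is.null(f$test$auc)) round(f$test$auc, 3) else NA,
               stringsAsFactors = FALSE)
  }))
  cat(sprintf("<raman_model_suite> %d binary models\n", length(x)))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Four-class surgical-guidance model
#'
#' Trains the multi-class model over the four structures encountered at the
#' sella during adenoma resection: pituitary gland, sella turcica bone, optic
#' chiasm and sella turcica dura.
#'
#' @param ds A processed, quality-gated [raman_set()].
#' @param seed Seed.
#' @param ... Passed to [raman_svm()].
#' @return A `raman_svm` fit.
#' @export
run_model_II <- function(ds, seed = 1, ...) {
  raman_svm(ds, "four_class", seed = seed, ...)
}

#' Score ex-situ / in-section gland spectra with an in-situ model
#'
#' Applies a model trained solely on in-situ measurements to gland records
#' acquired under the other preparation methods, reporting the predicted
#' class counts (one confusion-matrix row per method). Head-disjointness is
#' deliberately not required here: the point is robustness to the acquisition
#' method, not to new subjects.
#'
#' @param model A [raman_svm()] fit (typically the four-class model).
#' @param ds A [raman_set()] whose non-in-situ records are all pituitary
#'   gland (anything else is a task error).
#' @return A `transfer_report`: per-method predicted-class counts and
#'   gland-recall rates.
#' @export
transfer_to_methods <- function(model, ds) {
  stopifnot(inherits(model, "raman_svm"), inherits(ds, "raman_set"))
  sel <- ds$meta$prep_method != "in_situ"
  if (any(ds$meta$tissue[sel] != "pituitary_gland"))
    abort_task("non-gland records among the ex-situ/in-section spectra")
  rows <- list(); recall <- c()
  for (m in c("ex_situ", "in_section")) {
    k <- sel & ds$meta$prep_method == m
    if (!any(k)) {
      warning(sprintf("no %s gland records to score", m), call. = FALSE)
      next
    }
    pred <- predict(model, subset_records(ds, k))
    rows[[m]] <- table(factor(pred, levels = model$classes))
    recall[m] <- mean(pred == "pituitary_gland")
  }
  structure(list(counts = rows, gland_recall = recall,
                 n = vapply(rows, sum, numeric(1))),
            class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat("<transfer_report> in-situ-trained model applied to other preparations\n")
  for (m in names(x$counts)) {
    cat(sprintf("  %s (n = %d, gland recall %.3f):\n", m, x$n[[m]],
                x$gland_recall[[m]]))
    print(x$counts[[m]])
  }
  invisible(x)
}
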