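# Two-stage classification scheme: subject-disjoint splitting, peak-region
# pre-selection, sparse L1 feature selection, and an L2 linear SVM decision
# stage tuned by stratified fivefold cross-validation.

#' Head-disjoint train/test split
#'
#' Enumerates subsets of heads whose record share falls inside
#' `fraction`, keeps the one closest to the midpoint (ties broken by a seeded
#' draw), and never splits a head across train and test. If no subset is
#' feasible, the nearest-fraction plan is returned with `feasible = FALSE`
#' and a warning.
#'
#' @param ds A [raman_set()] (or its meta data frame).
#' @param fraction Target test-record share, default `c(0.33, 0.40)`.
#' @param seed Seed for tie-breaking.
#' @return A `split_plan`: `train_heads`, `test_heads`, `test_fraction`,
#'   `feasible`.
#' @export
split_by_head <- function(ds, fraction = c(0.33, 0.40), seed = 1) {
  meta <- if (inherits(ds, "raman_set")) ds$meta else ds
  heads <- sort(unique(meta$head_id))
  if (length(heads) < 2) abort_insufficient("need records from at least 2 heads")
  counts <- vapply(heads, function(h) sum(meta$head_id == h), numeric(1))
  total <- sum(counts)
  k <- length(heads)
  subsets <- utils::combn(k, 1, simplify = FALSE)
  for (m in 2:(k - 1)) if (k > 2)
    subsets <- c(subsets, utils::combn(k, m, simplify = FALSE))
  frac <- vapply(subsets, function(s) sum(counts[s]) / total, numeric(1))
  mid <- mean(fraction)
  ok <- frac >= fraction[1] & frac <= fraction[2]
  feasible <- any(ok)
  if (!feasible) {
    warning(sprintf(
      "no head subset achieves a test fraction in [%.2f, %.2f]; using nearest (%.2f)",
      fraction[1], fraction[2], frac[which.min(abs(frac - mid))]), call. = FALSE)
    cand <- which(abs(frac - mid) == min(abs(frac - mid)))
  } else {
    d <- abs(frac - mid); d[!ok] <- Inf
    cand <- which(d == min(d))
  }
  pick <- if (length(cand) > 1) {
    with_seed(seed, cand[sample.int(length(cand), 1)])
  } else cand
  test_heads <- heads[subsets[[pick]]]
  structure(list(train_heads = setdiff(heads, test_heads),
                 test_heads = test_heads,
                 test_fraction = frac[pick], feasible = feasible),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train heads {%s} | test heads {%s} (test fraction %.3f%s)\n",
              paste(x$train_heads, collapse = ","),
              paste(x$test_heads, collapse = ","),
              x$test_fraction, if (x$feasible) "" else ", infeasible target"))
  invisible(x)
}

# Run expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Candidate-bin mask around known Raman peaks
#'
#' Restricts modelling features to bins within `halfwidth` of a known band
#' center, preventing the selection stage from latching onto bins that carry
#' only stochastic noise. Centers outside the axis are dropped with a
#' message.
#'
#' @param shifts Wavenumber axis (cm-1).
#' @param centers Band centers (cm-1), e.g. from [default_band_registry()].
#' @param halfwidth Half-width of each region in cm-1 (default 25).
#' @return Integer vector of candidate bin indices.
#' @export
peak_mask <- function(shifts, centers, halfwidth = 25) {
  if (!length(centers)) abort_param("band registry is empty")
  shifts <- as_shifts(shifts)
  inside <- centers >= min(shifts) - halfwidth & centers <= max(shifts) + halfwidth
  if (any(!inside))
    message(sprintf("peak_mask: dropping %d center(s) outside the axis: %s",
                    sum(!inside), paste(centers[!inside], collapse = ", ")))
  centers <- centers[inside]
  keep <- rep(FALSE, length(shifts))
  for (c0 in centers) keep <- keep | abs(shifts - c0) <= halfwidth
  idx <- which(keep)
  if (!length(idx)) abort_param("peak mask is empty on this axis")
  idx
}

stratified_folds <- function(y, k = 5, seed = 1) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Sparse L1 feature selection
#'
#' Fits an L1-penalized linear classifier (lasso; grouped-multinomial for
#' more than two classes) on the masked bins over a logarithmic penalty grid,
#' scores each penalty by stratified fivefold cross-validated accuracy, and
#' keeps the strongest-accuracy penalty whose active set stays below
#' `max_features`. The selected bins are those with the largest absolute
#' coefficients; if no penalty meets the sparsity bound, the top
#' `max_features - 1` coefficients at the best-accuracy penalty are taken
#' (ties broken toward lower wavenumber).
#'
#' @param x Training spectra matrix (records x bins).
#' @param y Class labels (factor or character).
#' @param shifts Wavenumber axis matching `x` columns.
#' @param mask Candidate bin indices from [peak_mask()].
#' @param max_features Sparsity bound: strictly fewer than this many bins are
#'   returned (default 20).
#' @param lambda Decreasing penalty grid (default `10^seq(3, -3, length 25)`).
#' @param nfolds CV folds (default 5).
#' @param seed Fold-assignment seed.
#' @return List: `idx` (column indices into `x`), `bins` (shift values),
#'   `lambda`, `cv_accuracy`, `uninformative` flag.
#' @export
select_features_l1 <- function(x, y, shifts, mask = seq_len(ncol(x)),
                               max_features = 20,
                               lambda = 10^seq(3, -3, length.out = 25),
                               nfolds = 5, seed = 1) {
  y <- factor(y)
  if (nlevels(y) < 2) abort_task("need at least two classes in training data")
  xm <- x[, mask, drop = FALSE]
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  gargs <- if (fam == "multinomial") list(type.multinomial = "grouped") else list()
  lambda <- sort(lambda, decreasing = TRUE)

  fit_path <- function(xx, yy) do.call(glmnet::glmnet, c(list(
    x = xx, y = yy, family = fam, lambda = lambda, standardize = TRUE), gargs))

  # feature-level absolute coefficients at each lambda (max over classes)
  coef_mat <- function(fit, s) {
    cf <- glmnet::coef.glmnet(fit, s = s)
    if (fam == "binomial") abs(as.numeric(cf)[-1])
    else apply(vapply(cf, function(m) abs(as.numeric(m)[-1]),
                      numeric(ncol(xm))), 1, max)
  }

  folds <- stratified_folds(y, nfolds, seed)
  acc <- matrix(NA_real_, nfolds, length(lambda))
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    fit <- fit_path(xm[tr, , drop = FALSE], y[tr])
    pr <- stats::predict(fit, xm[!tr, , drop = FALSE], s = lambda, type = "class")
    acc[f, ] <- colMeans(pr == as.character(y[!tr]))
  }
  macc <- colMeans(acc)

  full <- fit_path(xm, y)
  nnz <- vapply(seq_along(lambda), function(i)
    sum(coef_mat(full, lambda[i]) > 0), numeric(1))

  okl <- nnz >= 1 & nnz < max_features
  if (any(okl)) {
    score <- macc; score[!okl] <- -Inf
    # ties on CV accuracy resolve toward the stronger penalty (sparser set),
    # honouring the sparsity-promoting intent of the selection stage
    best <- which(score == max(score))[1]
    cf <- coef_mat(full, lambda[best])
    sel <- which(cf > 0)
  } else {
    best <- which(macc == max(macc))[1]
    cf <- coef_mat(full, lambda[best])
    ord <- order(-cf, shifts[mask])
    sel <- sort(ord[seq_len(min(max_features - 1, sum(cf > 0), length(ord)))])
    sel <- sel[cf[sel] > 0]
    if (!length(sel)) {  # fully null path: fall back to densest fit
      cf <- coef_mat(full, lambda[length(lambda)])
      ord <- order(-cf, shifts[mask])
      sel <- sort(ord[seq_len(min(max_features - 1, max(sum(cf > 0), 1)))])
    }
  }
  if (length(sel) >= max_features) {
    ord <- order(-cf[sel], shifts[mask][sel])
    sel <- sort(sel[ord[seq_len(max_features - 1)]])
  }
  # flagged uninformative when the best CV accuracy is within two binomial
  # standard errors of the majority-class rate (grid-maximum optimism included)
  chance <- max(table(y)) / length(y)
  se <- sqrt(chance * (1 - chance) / length(y))
  list(idx = mask[sel], bins = shifts[mask][sel], lambda = lambda[best],
       cv_accuracy = macc[best],
       uninformative = macc[best] <= chance + 2 * se)
}

# One linear SVM with a sign-aligned decision score: higher score ->
# first level of y ("positive" class).
linear_svm_scored <- function(x, y, cost, class_weights = NULL) {
  m <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                  class.weights = class_weights)
  w <- as.numeric(crossprod(m$coefs, m$SV))
  score <- as.numeric(x %*% w) - m$rho
  pred <- stats::predict(m, x)
  pos <- levels(y)[1]
  flip <- mean(score[pred == pos]) < mean(score[pred != pos])
  if (is.na(flip)) flip <- FALSE  # degenerate: single predicted class
  if (flip) { w <- -w; rho <- -m$rho } else rho <- m$rho
  list(model = m, w = w, rho = rho,
       score = function(newx) as.numeric(newx %*% w) - rho)
}

ovr_fit <- function(x, y, cost, class_weights = NULL) {
  lapply(levels(y), function(cl) {
    y2 <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    cw <- if (is.null(class_weights)) NULL else {
      tb <- table(y2); stats::setNames(as.numeric(sum(tb) / (2 * tb)), names(tb))
    }
    linear_svm_scored(x, y2, cost, cw)
  })
}

ovr_scores <- function(models, newx) {
  matrix(vapply(models, function(m) m$score(newx), numeric(nrow(newx))),
         nrow = nrow(newx))
}

#' L2 linear SVM decision stage
#'
#' Trains the final L2-regularized linear SVM on the selected bins, tuning
#' the cost over a logarithmic grid by seeded, class-stratified fivefold
#' cross-validated accuracy. Multi-class tasks use one-vs-rest linear SVMs
#' with an argmax decision. The validation confusion matrix aggregates the
#' out-of-fold predictions at the chosen cost.
#'
#' @param x Training matrix restricted to the selected bins.
#' @param y Class labels.
#' @param costs Cost grid (default `10^(-3:3)`).
#' @param nfolds CV folds (default 5).
#' @param seed Fold-assignment seed.
#' @param class_weights If `TRUE`, inverse-frequency class weights (off by
#'   default).
#' @return List: `cost`, `cv_accuracy`, `cv_confusion` (aggregated over
#'   folds), `models`, `classes`, `binary`.
#' @export
fit_l2 <- function(x, y, costs = 10^(-3:3), nfolds = 5, seed = 1,
                   class_weights = FALSE) {
  y <- factor(y)
  if (nlevels(y) < 2) abort_task("need at least two classes in training data")
  if (any(table(y) < nfolds))
    abort_task("every class needs at least as many records as CV folds")
  if (!ncol(x)) abort_param("no selected bins to fit on")
  binary <- nlevels(y) == 2
  cw <- if (isTRUE(class_weights)) {
    tb <- table(y)
    stats::setNames(as.numeric(sum(tb) / (nlevels(y) * tb)), names(tb))
  } else NULL

  folds <- stratified_folds(y, nfolds, seed)
  oof <- matrix(NA_character_, length(y), length(costs))
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    for (ci in seq_along(costs)) {
      if (binary) {
        m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = costs[ci], scale = FALSE, class.weights = cw)
        oof[!tr, ci] <- as.character(stats::predict(m, x[!tr, , drop = FALSE]))
      } else {
        ms <- ovr_fit(x[tr, , drop = FALSE], y[tr], costs[ci], cw)
        sc <- ovr_scores(ms, x[!tr, , drop = FALSE])
        oof[!tr, ci] <- levels(y)[max.col(sc, ties.method = "first")]
      }
    }
  }
  accs <- colMeans(oof == as.character(y))
  best <- which.max(accs)  # ties -> smaller cost
  cv_conf <- table(truth = y, predicted = factor(oof[, best], levels = levels(y)))

  models <- if (binary) {
    list(linear_svm_scored(x, y, costs[best], cw))
  } else ovr_fit(x, y, costs[best], cw)

  list(cost = costs[best], cv_accuracy = accs[best], cv_confusion = cv_conf,
       models = models, classes = levels(y), binary = binary)
}

predict_l2 <- function(l2, newx, type = c("class", "score")) {
  type <- match.arg(type)
  if (l2$binary) {
    sc <- l2$models[[1]]$score(newx)
    if (type == "score") return(sc)
    factor(ifelse(sc > 0, l2$classes[1], l2$classes[2]), levels = l2$classes)
  } else {
    sc <- ovr_scores(l2$models, newx)
    colnames(sc) <- l2$classes
    if (type == "score") return(sc)
    factor(l2$classes[max.col(sc, ties.method = "first")], levels = l2$classes)
  }
}

confusion_stats <- function(conf) {
  classes <- rownames(conf)
  sens <- diag(conf) / pmax(rowSums(conf), 1)
  spec <- vapply(seq_along(classes), function(i) {
    tn <- sum(conf[-i, -i]); fp <- sum(conf[-i, i])
    if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  }, numeric(1))
  data.frame(class = classes, sensitivity = as.numeric(sens),
             specificity = spec, stringsAsFactors = FALSE)
}
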