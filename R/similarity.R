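#' Spectral angle mapper
#'
#' The angle between two spectra viewed as vectors in bin space,
#' `theta = arccos( sum(X*Y) / sqrt(sum(X^2) * sum(Y^2)) )`, reported in
#' degrees. Identical spectra give 0 deg, orthogonal spectra 90 deg; the
#' metric is invariant to positive rescaling of either argument. The arccos
#' argument is clipped to `[-1, 1]` for numerical safety (SNV fingerprints
#' can have negative dot products, so angles up to 180 deg are possible).
#'
#' @param x,y Numeric vectors of equal length (>= 2), neither all-zero.
#' @return Angle in degrees.
#' @export
sam <- function(x, y) {
  if (length(x) != length(y)) abort_structural("spectra must have equal length")
  if (length(x) < 2) abort_structural("spectra must have at least 2 bins")
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) abort_degenerate("SAM is undefined for a zero vector")
  acos(min(max(sum(x * y) / sqrt(sx * sy), -1), 1)) * 180 / pi
}

#' Mean spectrum and per-bin variance for one tissue
#'
#' @param ds A [raman_set()].
#' @param tissue Tissue label.
#' @param prep_method Optional preparation-method restriction.
#' @return List with `mean` and `variance` (population, 1/N) vectors over bins,
#'   and `n` records used.
#' @export
mean_spectrum <- function(ds, tissue, prep_method = NULL) {
  stopifnot(inherits(ds, "raman_set"))
  keep <- ds$meta$tissue == tissue
  if (!is.null(prep_method)) keep <- keep & ds$meta$prep_method == prep_method
  x <- ds$spectra[keep, , drop = FALSE]
  if (nrow(x) < 2)
    abort_insufficient(sprintf("need >= 2 records of '%s', found %d",
                               tissue, nrow(x)))
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  list(mean = mu, variance = pmax(v, 0), n = nrow(x))
}

#' Pairwise SAM matrix of tissue mean spectra
#'
#' @param ds A [raman_set()] with at least two tissues of >= 2 records each.
#' @return A `sam_matrix`: ordered labels, the symmetric angle matrix in
#'   degrees (zero diagonal), and the grand mean of off-diagonal angles.
#' @export
pairwise_sam <- function(ds) {
  stopifnot(inherits(ds, "raman_set"))
  tissues <- intersect(RAMAN_TISSUES, unique(ds$meta$tissue))
  tissues <- tissues[vapply(tissues, function(t)
    sum(ds$meta$tissue == t) >= 2, logical(1))]
  if (length(tissues) < 2)
    abort_insufficient("need mean spectra of at least two tissues")
  means <- vapply(tissues, function(t) mean_spectrum(ds, t)$mean,
                  numeric(ncol(ds$spectra)))
  k <- length(tissues)
  ang <- matrix(0, k, k, dimnames = list(tissues, tissues))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    ang[i, j] <- ang[j, i] <- sam(means[, i], means[, j])
  structure(list(labels = tissues, angles = ang,
                 mean_offdiag = mean(ang[upper.tri(ang)])),
            class = "sam_matrix")
}

#' @export
print.sam_matrix <- function(x, digits = 1, ...) {
  cat(sprintf("<sam_matrix> %d groups, mean off-diagonal angle %.1f deg\n",
              length(x$labels), x$mean_offdiag))
  print(round(x$angles, digits))
  invisible(x)
}

#' Record-level within- and between-tissue SAM distributions
#'
#' Computes the SAM angle for every pair of individual records and groups the
#' angles into within-tissue and between-tissue sets, with summary quantiles.
#' The overlap fraction (the share of within-tissue angles exceeding the
#' between-tissue median) quantifies how unreliable raw spectral angles are
#' for classifying single noisy measurements.
#'
#' @param ds A [raman_set()].
#' @return List with data frames `within` (`tissue`, `angle`) and `between`
#'   (`tissue_a`, `tissue_b`, `angle`), a `summary` of quantiles, and
#'   `overlap_fraction`.
#' @export
within_between_sam <- function(ds) {
  stopifnot(inherits(ds, "raman_set"))
  n <- nrow(ds$spectra)
  if (n < 2) abort_insufficient("need at least two records")
  # Angles via the normalized Gram matrix: far cheaper than pairwise sam().
  xn <- ds$spectra / sqrt(rowSums(ds$spectra^2))
  g <- pmin(pmax(tcrossprod(xn), -1), 1)
  ang <- acos(g) * 180 / pi
  tis <- ds$meta$tissue
  pairs <- which(upper.tri(ang), arr.ind = TRUE)
  a <- ang[pairs]
  same <- tis[pairs[, 1]] == tis[pairs[, 2]]
  within <- data.frame(tissue = tis[pairs[same, 1]], angle = a[same],
                       stringsAsFactors = FALSE)
  ta <- tis[pairs[!same, 1]]; tb <- tis[pairs[!same, 2]]
  t1 <- ifelse(ta < tb, ta, tb)
  t2 <- ifelse(ta < tb, tb, ta)
  between <- data.frame(tissue_a = t1, tissue_b = t2, angle = a[!same],
                        stringsAsFactors = FALSE)
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  summ <- rbind(
    if (nrow(within)) data.frame(group = "within",
                                 t(stats::quantile(within$angle, qs))),
    if (nrow(between)) data.frame(group = "between",
                                  t(stats::quantile(between$angle, qs))))
  overlap <- if (nrow(within) && nrow(between))
    mean(within$angle > stats::median(between$angle)) else NA_real_
  list(within = within, between = between, summary = summ,
       overlap_fraction = overlap)
}

#' Compare gland preparation methods
#'
#' For pituitary-gland records, reports the total spectral variance (per-bin
#' population variance summed over bins) of each preparation method and the
#' SAM angles among the three method mean spectra, per head and pooled across
#' heads.
#'
#' @param ds A [raman_set()] containing gland records of >= 2 methods.
#' @return List of data frames `variance` (`head`, `method`,
#'   `total_variance`, `n`) and `sam` (`head`, `method_a`, `method_b`,
#'   `angle`); pooled rows carry `head = "pooled"`.
#' @export
prep_method_comparison <- function(ds) {
  stopifnot(inherits(ds, "raman_set"))
  ds <- subset_records(ds, ds$meta$tissue == "pituitary_gland")
  methods <- intersect(RAMAN_PREP_METHODS, unique(ds$meta$prep_method))
  if (length(methods) < 2)
    abort_insufficient("need gland records of at least two preparation methods")

  rows_for <- function(sub, label) {
    vr <- NULL; sm <- NULL
    means <- list()
    for (m in methods) {
      k <- sub$meta$prep_method == m
      if (sum(k) < 2) next
      ms <- mean_spectrum(sub, "pituitary_gland", m)
      means[[m]] <- ms$mean
      vr <- rbind(vr, data.frame(head = label, method = m,
                                 total_variance = sum(ms$variance), n = ms$n,
                                 stringsAsFactors = FALSE))
    }
    mm <- names(means)
    if (length(mm) >= 2)
      for (i in seq_len(length(mm) - 1)) for (j in (i + 1):length(mm))
        sm <- rbind(sm, data.frame(head = label, method_a = mm[i],
                                   method_b = mm[j],
                                   angle = sam(means[[mm[i]]], means[[mm[j]]]),
                                   stringsAsFactors = FALSE))
    list(vr = vr, sm = sm)
  }

  out_v <- NULL; out_s <- NULL
  for (h in sort(unique(ds$meta$head_id))) {
    res <- rows_for(subset_records(ds, ds$meta$head_id == h), as.character(h))
    out_v <- rbind(out_v, res$vr); out_s <- rbind(out_s, res$sm)
  }
  res <- rows_for(ds, "pooled")
  out_v <- rbind(out_v, res$vr); out_s <- rbind(out_s, res$sm)
  list(variance = out_v, sam = out_s)
}
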