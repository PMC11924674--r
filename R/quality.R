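#' Spectral quality factor
#'
#' The average signed squared intensity of an SNV-normalized fingerprint,
#' `QF = (1/N) * sum(sgn(r_i) * r_i^2)`. Pure stochastic noise gives QF near
#' 0; a spectrum dominated by a few large narrow peaks approaches 1. Because
#' the input has unit population standard deviation (`sum(r^2) = N`), QF is
#' bounded in `(-1, (N-2)/N]`.
#'
#' @param r SNV-normalized intensities (mean 0, unit population sd).
#' @param tol Tolerance on the SNV precondition.
#' @return The quality factor, a single number.
#' @export
quality_factor <- function(r, tol = 1e-6) {
  if (inherits(r, "processed_spectrum")) r <- r$intensities
  m <- mean(r)
  s <- sqrt(mean((r - m)^2))
  if (abs(m) > tol || abs(s - 1) > tol)
    abort_contract(sprintf(
      "quality_factor requires SNV-normalized input (mean %.3g, pop. sd %.6g)",
      m, s))
  mean(sign(r) * r^2)
}

#' Gate a dataset on the quality factor
#'
#' Computes the QF of every record and keeps those with `QF >= threshold`
#' (the boundary is inclusive). Records below threshold are eliminated and
#' summarized per tissue.
#'
#' @param ds A [raman_set()].
#' @param threshold QF cutoff (default 0.3).
#' @return List with `dataset` (the kept records, QF filled into the
#'   metadata) and `report` (a `qf_report`: per-record QFs, kept/eliminated
#'   keys, and per-tissue counts before/after gating).
#' @export
gate_quality <- function(ds, threshold = 0.3) {
  stopifnot(inherits(ds, "raman_set"))
  qf <- apply(ds$spectra, 1, quality_factor)
  ds$meta$qf <- as.numeric(qf)
  keep <- qf >= threshold
  keys <- rownames(ds$meta)
  before <- table(factor(ds$meta$tissue, levels = RAMAN_TISSUES))
  after <- table(factor(ds$meta$tissue[keep], levels = RAMAN_TISSUES))
  kept_ds <- subset_records(ds, keep)
  if (!any(keep))
    warning("quality gate eliminated every record", call. = FALSE)
  report <- structure(list(
    threshold = threshold,
    qf = stats::setNames(as.numeric(qf), keys),
    kept = keys[keep], eliminated = keys[!keep],
    class_balance = data.frame(
      tissue = RAMAN_TISSUES,
      n_before = as.integer(before), n_after = as.integer(after))),
    class = "qf_report")
  list(dataset = kept_ds, report = report)
}

#' @export
print.qf_report <- function(x, ...) {
  cat(sprintf("<qf_report> threshold %.2f: kept %d, eliminated %d of %d records\n",
              x$threshold, length(x$kept), length(x$eliminated),
              length(x$qf)))
  bal <- x$class_balance[x$class_balance$n_before > 0, ]
  if (nrow(bal)) print(bal, row.names = FALSE)
  invisible(x)
}
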