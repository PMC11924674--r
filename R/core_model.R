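#' Tissue labels probed in the sellar-region protocol
#'
#' The closed set of nine anatomical structures sampled by the endonasal
#' probe protocol: the pituitary gland, its surgical neighbours (sella
#' turcica bone and dura, optic chiasm, sphenoid bone), the nasal corridor
#' (septum, mucosa) and cerebral reference tissue (white and gray matter).
#'
#' @format Character vector of length 9.
#' @export
RAMAN_TISSUES <- c(
  "pituitary_gland", "optic_chiasm", "st_bone", "st_dura",
  "sphenoid_bone", "nasal_septum", "nasal_mucosa",
  "white_matter", "gray_matter"
)

#' Pituitary-gland preparation methods
#'
#' Gland spectra are acquired in place (`in_situ`), on the excised gland
#' (`ex_situ`), and on ~2 mm axial slices (`in_section`). All other tissues
#' are measured `in_situ` only.
#'
#' @format Character vector of length 3.
#' @export
RAMAN_PREP_METHODS <- c("in_situ", "ex_situ", "in_section")

#' Construct a wavenumber axis
#'
#' @param shifts Strictly increasing, finite Raman shifts in cm-1.
#' @param nominal_resolution Instrument spectral resolution in cm-1
#'   (full width, not bin spacing). Default 8.7.
#' @return An object of class `spectral_axis`.
#' @export
spectral_axis <- function(shifts, nominal_resolution = 8.7) {
  shifts <- as.numeric(shifts)
  if (length(shifts) < 2L || any(!is.finite(shifts)))
    abort_structural("axis shifts must be finite and of length >= 2")
  if (any(diff(shifts) <= 0))
    abort_structural("axis shifts must be strictly increasing")
  if (!is.numeric(nominal_resolution) || nominal_resolution <= 0)
    abort_param("nominal_resolution must be a positive number")
  structure(list(shifts = shifts, nominal_resolution = nominal_resolution),
            class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d bins, %.1f-%.1f cm-1 (resolution %.1f cm-1)\n",
              length(x$shifts), min(x$shifts), max(x$shifts),
              x$nominal_resolution))
  invisible(x)
}

as_shifts <- function(axis) {
  if (inherits(axis, "spectral_axis")) axis$shifts else as.numeric(axis)
}

#' Acquisition metadata
#'
#' @param head_id Integer subject (head) identifier.
#' @param tissue One of [RAMAN_TISSUES].
#' @param prep_method One of [RAMAN_PREP_METHODS]; anything other than
#'   `"in_situ"` is only permitted for the pituitary gland.
#' @param exposure_time_s Exposure time in seconds (positive; the acquisition
#'   protocol uses 3-11 s).
#' @param laser_power_mw On-tissue laser power in mW, fixed at 40 by protocol.
#' @param replicate Replicate index within (head, tissue, prep_method).
#' @return A list of class `acquisition_meta`.
#' @export
acquisition_meta <- function(head_id, tissue, prep_method = "in_situ",
                             exposure_time_s = 5, laser_power_mw = 40,
                             replicate = 1L) {
  if (!tissue %in% RAMAN_TISSUES)
    abort_vocab(sprintf("unknown tissue label '%s' (must be one of: %s)",
                        tissue, paste(RAMAN_TISSUES, collapse = ", ")))
  if (!prep_method %in% RAMAN_PREP_METHODS)
    abort_vocab(sprintf("unknown prep_method '%s'", prep_method))
  if (prep_method != "in_situ" && tissue != "pituitary_gland")
    abort_schema("prep_method other than in_situ is only valid for pituitary_gland")
  if (!is.finite(exposure_time_s) || exposure_time_s <= 0)
    abort_param("exposure_time_s must be positive")
  if (!is.finite(laser_power_mw) || laser_power_mw <= 0)
    abort_param("laser_power_mw must be positive")
  structure(list(head_id = as.integer(head_id), tissue = tissue,
                 prep_method = prep_method,
                 exposure_time_s = as.numeric(exposure_time_s),
                 laser_power_mw = as.numeric(laser_power_mw),
                 replicate = as.integer(replicate)),
            class = "acquisition_meta")
}

record_key <- function(meta) {
  sprintf("h%02d_%s_%s_r%03d", meta$head_id, meta$tissue, meta$prep_method,
          meta$replicate)
}

#' Raw spectroscopic acquisition
#'
#' One probe measurement: a stack of CCD accumulation frames plus the dark
#' frame acquired with the laser off.
#'
#' @param frames Numeric matrix, accumulations x pixels, in counts.
#' @param dark_frame Numeric vector of dark counts, one per pixel.
#' @param meta An [acquisition_meta()].
#' @param saturation CCD saturation ceiling in counts (default 65535).
#' @return A list of class `raw_acquisition`.
#' @export
raw_acquisition <- function(frames, dark_frame, meta, saturation = 65535) {
  frames <- as.matrix(frames)
  if (length(dark_frame) != ncol(frames))
    abort_structural(sprintf(
      "dark_frame length (%d) does not match frame pixel count (%d)",
      length(dark_frame), ncol(frames)))
  if (any(!is.finite(frames)) || any(!is.finite(dark_frame)))
    abort_structural("frame counts must be finite")
  if (any(frames < 0) || any(dark_frame < 0))
    abort_structural("counts must be >= 0")
  if (any(frames > saturation) || any(dark_frame > saturation))
    abort_structural("counts exceed the saturation ceiling")
  if (!inherits(meta, "acquisition_meta"))
    abort_schema("meta must be an acquisition_meta object")
  structure(list(frames = frames, dark_frame = as.numeric(dark_frame),
                 meta = meta, saturation = saturation,
                 axis_pixels = ncol(frames)),
            class = "raw_acquisition")
}

#' Processed spectral fingerprint
#'
#' An SNV-normalized spectrum on the truncated 800-1800 cm-1 grid. The SNV
#' contract (zero mean, unit population standard deviation) is validated on
#' construction.
#'
#' @param axis A [spectral_axis()] restricted to the fingerprint window.
#' @param intensities SNV-normalized intensities, one per axis bin.
#' @param meta An [acquisition_meta()].
#' @param qf Optional quality factor (filled by [gate_quality()]).
#' @param tol Numerical tolerance on the SNV contract.
#' @return A list of class `processed_spectrum`.
#' @export
processed_spectrum <- function(axis, intensities, meta, qf = NA_real_,
                               tol = 1e-9) {
  shifts <- as_shifts(axis)
  if (length(intensities) != length(shifts))
    abort_structural("intensities length does not match axis length")
  if (min(shifts) < 800 - 1e-9 || max(shifts) > 1800 + 1e-9)
    abort_structural("processed axis must lie within [800, 1800] cm-1")
  m <- mean(intensities)
  s <- sqrt(mean((intensities - m)^2))
  if (abs(m) > tol || abs(s - 1) > tol)
    abort_contract(sprintf(
      "intensities violate the SNV contract (mean %.3g, pop. sd %.6g)", m, s))
  if (!inherits(meta, "acquisition_meta"))
    abort_schema("meta must be an acquisition_meta object")
  structure(list(axis = if (inherits(axis, "spectral_axis")) axis else
                   spectral_axis(shifts),
                 intensities = as.numeric(intensities),
                 qf = qf, meta = meta),
            class = "processed_spectrum")
}

meta_as_row <- function(meta, qf = NA_real_) {
  data.frame(head_id = meta$head_id, tissue = meta$tissue,
             prep_method = meta$prep_method, replicate = meta$replicate,
             exposure_time_s = meta$exposure_time_s,
             laser_power_mw = meta$laser_power_mw, qf = qf,
             stringsAsFactors = FALSE)
}

check_unique_keys <- function(keys) {
  dup <- keys[duplicated(keys)]
  if (length(dup))
    abort_schema(sprintf("duplicate record keys: %s",
                         paste(unique(dup), collapse = ", ")))
}

#' Raw dataset container
#'
#' @param acquisitions List of [raw_acquisition()] objects.
#' @param provenance List recording how the dataset was produced (generator
#'   seed and configuration, or source file paths).
#' @return A list of class `raman_raw_set`.
#' @export
raman_raw_set <- function(acquisitions, provenance = list()) {
  if (!length(acquisitions))
    return(structure(list(acquisitions = list(), provenance = provenance),
                     class = "raman_raw_set"))
  ok <- vapply(acquisitions, inherits, logical(1), "raw_acquisition")
  if (!all(ok)) abort_schema("all records must be raw_acquisition objects")
  keys <- vapply(acquisitions, function(a) record_key(a$meta), character(1))
  check_unique_keys(keys)
  names(acquisitions) <- keys
  structure(list(acquisitions = acquisitions, provenance = provenance),
            class = "raman_raw_set")
}

#' @export
print.raman_raw_set <- function(x, ...) {
  cat(sprintf("<raman_raw_set> %d acquisitions\n", length(x$acquisitions)))
  if (length(x$acquisitions)) {
    tiss <- vapply(x$acquisitions, function(a) a$meta$tissue, character(1))
    print(table(tissue = tiss))
  }
  invisible(x)
}

#' Processed dataset container
#'
#' Holds SNV-normalized fingerprints on a shared truncated axis together with
#' per-record metadata. The SNV contract is validated for every row.
#'
#' @param axis Shared [spectral_axis()].
#' @param spectra Numeric matrix, records x bins.
#' @param meta `data.frame` with columns head_id, tissue, prep_method,
#'   replicate, exposure_time_s, laser_power_mw and qf.
#' @param provenance Provenance list (seed/config or file paths).
#' @param tol Tolerance on the per-record SNV contract.
#' @return A list of class `raman_set`.
#' @export
raman_set <- function(axis, spectra, meta, provenance = list(), tol = 1e-9) {
  shifts <- as_shifts(axis)
  spectra <- as.matrix(spectra)
  if (nrow(meta) != nrow(spectra))
    abort_structural("meta rows must match spectra rows")
  if (nrow(spectra) > 0 && ncol(spectra) != length(shifts))
    abort_structural("spectra columns must match axis length")
  need <- c("head_id", "tissue", "prep_method", "replicate",
            "exposure_time_s", "laser_power_mw")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    abort_schema(sprintf("metadata missing field(s): %s",
                         paste(miss, collapse = ", ")))
  if (!"qf" %in% names(meta)) meta$qf <- NA_real_
  bad <- setdiff(unique(meta$tissue), RAMAN_TISSUES)
  if (length(bad))
    abort_vocab(sprintf("unknown tissue label(s): %s", paste(bad, collapse = ", ")))
  if (nrow(meta)) {
    keys <- sprintf("h%02d_%s_%s_r%03d", meta$head_id, meta$tissue,
                    meta$prep_method, meta$replicate)
    check_unique_keys(keys)
    rownames(spectra) <- keys
    rownames(meta) <- keys
    m <- rowMeans(spectra)
    s <- sqrt(rowMeans((spectra - m)^2))
    if (any(abs(m) > tol) || any(abs(s - 1) > tol))
      abort_contract("one or more spectra violate the SNV contract")
  }
  structure(list(axis = if (inherits(axis, "spectral_axis")) axis else
                   spectral_axis(shifts),
                 spectra = spectra, meta = meta, provenance = provenance),
            class = "raman_set")
}

#' @export
print.raman_set <- function(x, ...) {
  cat(sprintf("<raman_set> %d spectra x %d bins (%.0f-%.0f cm-1)\n",
              nrow(x$spectra), length(x$axis$shifts),
              min(x$axis$shifts), max(x$axis$shifts)))
  if (nrow(x$meta)) print(table(tissue = x$meta$tissue))
  invisible(x)
}

#' Subset a processed dataset by metadata predicate
#'
#' @param ds A [raman_set()].
#' @param keep Logical vector over records.
#' @return A [raman_set()] with the selected records.
#' @export
subset_records <- function(ds, keep) {
  stopifnot(inherits(ds, "raman_set"))
  keep <- which(keep)
  raman_set(ds$axis, ds$spectra[keep, , drop = FALSE],
            ds$meta[keep, , drop = FALSE], ds$provenance)
}

n_records <- function(ds) {
  if (inherits(ds, "raman_set")) nrow(ds$spectra) else length(ds$acquisitions)
}
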