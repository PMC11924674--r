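#' Preprocessing parameters
#'
#' Defaults follow the acquisition protocol: a 50 cm-1 minimum bubble for
#' baseline removal, a Savitzky-Golay filter of order 3 with window 1 (an
#' exact no-op, kept configurable), truncation to the 800-1800 cm-1
#' fingerprint window, an 8-MAD cosmic-ray threshold and a quadratic
#' pixel-to-wavenumber calibration.
#'
#' @param bubble_min_width Minimum bubble width in cm-1 (> 0).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param sg_window Savitzky-Golay window (odd; 1 disables smoothing,
#'   otherwise must exceed `sg_order`).
#' @param truncate_lo,truncate_hi Fingerprint window bounds in cm-1.
#' @param despike_threshold Cosmic-ray threshold in MAD multiples.
#' @param calib_poly_degree Degree of the pixel-to-shift polynomial.
#' @param stage_order Internal guard: the stage order is fixed; passing
#'   anything other than `NULL` or the canonical order is an error.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(bubble_min_width = 50, sg_order = 3,
                              sg_window = 1, truncate_lo = 800,
                              truncate_hi = 1800, despike_threshold = 8,
                              calib_poly_degree = 2, stage_order = NULL) {
  if (bubble_min_width <= 0) abort_param("bubble_min_width must be > 0")
  if (truncate_lo >= truncate_hi) abort_param("truncate_lo must be < truncate_hi")
  if (sg_window %% 2 == 0) abort_param("sg_window must be odd")
  if (sg_window != 1 && sg_window <= sg_order)
    abort_param("sg_window must be 1 or greater than sg_order")
  if (despike_threshold <= 0) abort_param("despike_threshold must be > 0")
  canonical <- c("dark", "despike", "calibrate", "response", "average",
                 "baseline", "smooth", "truncate", "snv")
  if (!is.null(stage_order) && !identical(as.character(stage_order), canonical))
    abort_param("the preprocessing stage order is fixed and cannot be permuted")
  structure(list(bubble_min_width = bubble_min_width, sg_order = sg_order,
                 sg_window = sg_window, truncate_lo = truncate_lo,
                 truncate_hi = truncate_hi,
                 despike_threshold = despike_threshold,
                 calib_poly_degree = calib_poly_degree,
                 stage_order = canonical),
            class = "preprocess_params")
}

#' Calibration reference set
#'
#' Pairs detected pixel positions of acetaminophen reference peaks with their
#' known Raman shifts, plus a relative instrument-response curve measured on
#' a Raman intensity standard.
#'
#' @param reference_peak_pixels Pixel indices of detected reference peaks.
#' @param reference_peak_shifts Known shifts (cm-1) of the same peaks.
#' @param response_curve Strictly positive relative response, one value per
#'   detector pixel.
#' @return A list of class `calibration_set`.
#' @export
calibration_set <- function(reference_peak_pixels, reference_peak_shifts,
                            response_curve) {
  if (length(reference_peak_pixels) != length(reference_peak_shifts))
    abort_calibration("reference peak pixels and shifts must pair up")
  if (any(response_curve <= 0))
    abort_calibration("response curve must be strictly positive")
  structure(list(reference_peak_pixels = as.numeric(reference_peak_pixels),
                 reference_peak_shifts = as.numeric(reference_peak_shifts),
                 response_curve = as.numeric(response_curve)),
            class = "calibration_set")
}

# Acetaminophen reference Raman shifts (cm-1) inside the 400-2000 window.
APAP_SHIFTS <- c(651.6, 797.2, 857.9, 968.7, 1168.5, 1236.8, 1323.9, 1561.6, 1648.4)

#' Default calibration for the synthetic instrument
#'
#' The synthetic detector maps pixels linearly onto `shift_range`; the
#' acetaminophen reference peaks are placed at their exact pixel positions
#' under that mapping and the response curve is flat.
#'
#' @param n_pixels Detector pixel count.
#' @param shift_range Axis span in cm-1.
#' @return A [calibration_set()].
#' @export
default_calibration <- function(n_pixels = 1601, shift_range = c(400, 2000)) {
  px <- 1 + (APAP_SHIFTS - shift_range[1]) /
    (shift_range[2] - shift_range[1]) * (n_pixels - 1)
  calibration_set(px, APAP_SHIFTS, rep(1, n_pixels))
}

#' Subtract the dark frame from every accumulation
#'
#' @param raw A [raw_acquisition()], or a frames matrix plus `dark_frame`.
#' @param dark_frame Dark counts (ignored when `raw` is a raw_acquisition).
#' @return Matrix of dark-corrected frames (negative values permitted).
#' @export
subtract_dark <- function(raw, dark_frame = NULL) {
  if (inherits(raw, "raw_acquisition")) {
    frames <- raw$frames
    dark_frame <- raw$dark_frame
  } else frames <- as.matrix(raw)
  if (is.null(dark_frame)) abort_structural("dark_frame is required")
  if (length(dark_frame) != ncol(frames))
    abort_structural("dark_frame length does not match frame pixel count")
  sweep(frames, 2, dark_frame, "-")
}

# Column medians in one vectorized pass (columns sorted via a single order()).
col_medians <- function(m) {
  r <- nrow(m)
  s <- matrix(m[order(col(m), m)], nrow = r)
  if (r %% 2L == 1L) s[(r + 1L) %/% 2L, ] else (s[r %/% 2L, ] + s[r %/% 2L + 1L, ]) / 2
}

#' Remove cosmic-ray events from accumulation frames
#'
#' With two or more accumulations, each pixel's across-frame median and MAD
#' are computed; values exceeding the median by more than
#' `threshold * MAD` are replaced by the median (all other values are left
#' untouched). A single frame falls back to a within-spectrum running-median
#' despiker. Note the across-frame filter cannot remove a spike present at
#' the same pixel in at least half of the frames (the median then follows the
#' spike).
#'
#' @param frames Accumulations x pixels matrix.
#' @param threshold MAD multiples (default 8).
#' @return Despiked frames matrix.
#' @export
remove_cosmic_rays <- function(frames, threshold = 8) {
  frames <- as.matrix(frames)
  if (nrow(frames) >= 2) {
    med <- col_medians(frames)
    dev <- sweep(frames, 2, med, "-")
    mads <- 1.4826 * col_medians(abs(dev))
    lim <- rep(threshold * pmax(mads, .Machine$double.eps), each = nrow(frames))
    hit <- dev > lim
    frames[hit] <- med[col(frames)[hit]]
    frames
  } else {
    x <- frames[1, ]
    med <- stats::runmed(x, k = 5, endrule = "median")
    res <- x - med
    lim <- threshold * max(stats::mad(res), .Machine$double.eps)
    x[res > lim] <- med[res > lim]
    matrix(x, nrow = 1)
  }
}

#' Fit the pixel-to-wavenumber axis from reference peaks
#'
#' Least-squares polynomial of degree `degree` mapping detector pixel to
#' Raman shift, evaluated at all pixels. The fitted mapping must be strictly
#' increasing over the pixel range.
#'
#' @param calib A [calibration_set()].
#' @param n_pixels Number of detector pixels.
#' @param degree Polynomial degree (default 2).
#' @param nominal_resolution Passed through to the returned axis.
#' @return A [spectral_axis()] of length `n_pixels`.
#' @export
calibrate_axis <- function(calib, n_pixels, degree = 2,
                           nominal_resolution = 8.7) {
  stopifnot(inherits(calib, "calibration_set"))
  if (length(calib$reference_peak_pixels) < degree + 1)
    abort_calibration(sprintf(
      "need at least %d reference peaks for a degree-%d fit, got %d",
      degree + 1, degree, length(calib$reference_peak_pixels)))
  fit <- stats::lm(shift ~ stats::poly(pixel, degree, raw = TRUE),
                   data = data.frame(pixel = calib$reference_peak_pixels,
                                     shift = calib$reference_peak_shifts))
  shifts <- as.numeric(stats::predict(fit,
                                      newdata = data.frame(pixel = seq_len(n_pixels))))
  if (any(diff(shifts) <= 0))
    abort_calibration("fitted pixel-to-shift mapping is not strictly increasing")
  spectral_axis(shifts, nominal_resolution)
}

#' Divide out the instrument's relative response
#'
#' The response curve is rescaled to unit mean before division, so the
#' correction changes spectral shape but not overall scale; a constant
#' response is therefore an exact identity.
#'
#' @param spectrum Intensity vector (or frames matrix) on the pixel grid.
#' @param calib A [calibration_set()] whose `response_curve` covers the grid.
#' @return Corrected spectrum (same shape as input).
#' @export
correct_response <- function(spectrum, calib) {
  resp <- calib$response_curve
  if (any(resp <= 0)) abort_calibration("response curve must be strictly positive")
  npix <- if (is.matrix(spectrum)) ncol(spectrum) else length(spectrum)
  if (length(resp) != npix)
    abort_structural("response curve length does not match the pixel grid")
  resp <- resp / mean(resp)
  if (is.matrix(spectrum)) sweep(spectrum, 2, resp, "/") else spectrum / resp
}

#' Rolling-bubble baseline estimation
#'
#' Estimates the broad autofluorescence background as the upper envelope of
#' circular arcs ("bubbles") grown from below the spectrum. The endpoint
#' chord (tilt) is removed first, then the signal is rescaled so that its
#' intensity range equals its bin range (bubbles are circles in that
#' coordinate system). On each interval the spanning arc - a half-bubble
#' with its apex at the boundary for intervals touching a spectrum edge -
#' is lifted until it first touches the spectrum; the touch point splits the
#' interval and the recursion continues on sub-intervals no narrower than
#' `min_width` (applied on the wavenumber axis). A touch at an interval
#' endpoint shrinks the interval by one bin so the envelope can climb
#' structure wider than the bubble floor. Between adjacent contact points
#' closer than `min_width` the convex arc is capped by the straight chord
#' (the minimal admissible bridge). Intervals of fewer than two interior
#' bins keep the straight chord. The resulting baseline never exceeds the
#' spectrum and contains no feature narrower than `min_width`; the
#' remainder (`raman`) is non-negative, and a pure straight-line input
#' yields an identically zero remainder.
#'
#' @param spectrum Intensity vector on a monotone axis.
#' @param shifts Wavenumber axis (cm-1), same length.
#' @param min_width Minimum bubble width in cm-1 (default 50).
#' @return List with `raman` and `baseline` vectors.
#' @export
bubblefill_baseline <- function(spectrum, shifts, min_width = 50) {
  n <- length(spectrum)
  if (length(shifts) != n)
    abort_structural("spectrum and axis lengths differ")
  if (n < 2) abort_structural("spectrum must have at least 2 bins")
  if (any(diff(shifts) <= 0)) abort_structural("axis must be strictly increasing")
  if (min_width <= 0) abort_param("min_width must be > 0")

  # Remove the endpoint chord first so a tilted background does not distort
  # the bubble geometry (a pure straight line then yields zero raman signal).
  tilt <- spectrum[1] + (spectrum[n] - spectrum[1]) *
    (shifts - shifts[1]) / (shifts[n] - shifts[1])
  flat <- spectrum - tilt
  yr <- diff(range(flat))
  if (yr == 0)
    return(list(raman = numeric(n), baseline = spectrum))
  y0 <- min(flat)
  ys <- (flat - y0) / yr * (n - 1)              # square coordinate system
  spacing <- (shifts[n] - shifts[1]) / (n - 1)

  baseline <- rep(-Inf, n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    l <- iv[1]; r <- iv[2]
    idx <- l:r
    if (r - l < 2L) {                           # degenerate: straight chord
      baseline[idx] <- pmax(baseline[idx],
                            seq(ys[l], ys[r], length.out = r - l + 1L))
      next
    }
    # Half-bubbles at the spectrum edges (no anchor beyond the boundary),
    # centered bubbles elsewhere.
    if (l == 1L && r == n) {
      R <- (r - l) / 2; arc <- sqrt(pmax(R^2 - (idx - (l + r) / 2)^2, 0))
    } else if (l == 1L) {
      R <- r - l; arc <- sqrt(pmax(R^2 - (idx - l)^2, 0))
    } else if (r == n) {
      R <- r - l; arc <- sqrt(pmax(R^2 - (r - idx)^2, 0))
    } else {
      R <- (r - l) / 2; arc <- sqrt(pmax(R^2 - (idx - (l + r) / 2)^2, 0))
    }
    gap <- ys[idx] - arc
    lift <- min(gap)
    touch <- l + which.min(gap) - 1L
    baseline[idx] <- pmax(baseline[idx], arc + lift)
    # A touch at an interval endpoint cannot split it; shrink by one bin and
    # keep growing so the envelope can climb structure wider than the bubble.
    if (touch == l) {
      if ((shifts[r] - shifts[l + 1L]) >= min_width)
        stack[[length(stack) + 1L]] <- c(l + 1L, r)
    } else if (touch == r) {
      if ((shifts[r - 1L] - shifts[l]) >= min_width)
        stack[[length(stack) + 1L]] <- c(l, r - 1L)
    } else {
      if ((shifts[touch] - shifts[l]) >= min_width)
        stack[[length(stack) + 1L]] <- c(l, touch)
      if ((shifts[r] - shifts[touch]) >= min_width)
        stack[[length(stack) + 1L]] <- c(touch, r)
    }
  }
  # Between adjacent contact points closer than min_width no bubble can be
  # grown; the minimal admissible bridge there is the straight chord, so cap
  # the convex arc by it (the baseline stays contact-anchored and featureless
  # at sub-bubble scales, and sits lower under narrow peaks).
  contact <- which(ys - baseline <= 1e-9 * (n - 1))
  if (length(contact) >= 2) {
    for (k in seq_len(length(contact) - 1L)) {
      a <- contact[k]; b <- contact[k + 1L]
      if (b - a < 2L || (shifts[b] - shifts[a]) >= min_width) next
      seg <- a:b
      baseline[seg] <- pmin(baseline[seg],
                            seq(baseline[a], baseline[b], length.out = b - a + 1L))
    }
  }
  bl <- baseline / (n - 1) * yr + y0 + tilt
  bl <- pmin(bl, spectrum)                       # guard float round-off
  list(raman = spectrum - bl, baseline = bl)
}

#' Savitzky-Golay smoothing
#'
#' Standard Savitzky-Golay convolution; a window of 1 is an exact no-op (the
#' protocol default). The filter reproduces polynomials up to its order
#' exactly and contracts white noise.
#'
#' @param spectrum Intensity vector.
#' @param order Polynomial order (default 3).
#' @param window Odd window length (default 1).
#' @return Smoothed vector.
#' @export
smooth_sg <- function(spectrum, order = 3, window = 1) {
  if (window %% 2 == 0) abort_param("sg window must be odd")
  if (window == 1) return(spectrum)
  if (window <= order) abort_param("sg window must exceed the order")
  if (window > length(spectrum)) abort_param("sg window exceeds spectrum length")
  as.numeric(signal::sgolayfilt(spectrum, p = order, n = window))
}

#' Truncate a spectrum to a wavenumber window
#'
#' @param spectrum Intensity vector.
#' @param shifts Axis (cm-1).
#' @param lo,hi Window bounds; bins with `lo <= shift <= hi` are retained.
#' @return List with `intensities` and `shifts` of the retained bins.
#' @export
truncate_spectrum <- function(spectrum, shifts, lo = 800, hi = 1800) {
  keep <- which(shifts >= lo & shifts <= hi)
  if (!length(keep))
    abort_range(sprintf("no bins fall inside [%g, %g] cm-1", lo, hi))
  list(intensities = spectrum[keep], shifts = shifts[keep])
}

#' Standard normal variate normalization
#'
#' Centers and scales a spectrum to zero mean and unit population (1/N)
#' standard deviation.
#'
#' @param spectrum Intensity vector with non-zero spread.
#' @return Normalized vector.
#' @export
snv <- function(spectrum) {
  m <- mean(spectrum)
  s <- sqrt(mean((spectrum - m)^2))
  if (s <= .Machine$double.eps * max(1, abs(m)))
    abort_degenerate("constant spectrum cannot be SNV-normalized")
  (spectrum - m) / s
}

#' Full preprocessing chain for one acquisition
#'
#' Applies, in fixed order: dark subtraction, cosmic-ray removal, axis
#' calibration, response correction, accumulation averaging, rolling-bubble
#' baseline removal, Savitzky-Golay smoothing, truncation to the fingerprint
#' window, and SNV normalization. Errors raised by a stage are tagged with
#' the stage name. The quality factor is left unset; see [gate_quality()].
#'
#' @param raw A [raw_acquisition()].
#' @param calib A [calibration_set()].
#' @param params A [preprocess_params()].
#' @return A [processed_spectrum()].
#' @export
preprocess <- function(raw, calib = default_calibration(raw$axis_pixels),
                       params = preprocess_params()) {
  stopifnot(inherits(raw, "raw_acquisition"), inherits(params, "preprocess_params"))
  stage <- function(name, expr) {
    tryCatch(expr, raman_error = function(e) {
      raman_abort(sprintf("[stage %s] %s", name, conditionMessage(e)), class(e)[1])
    })
  }
  frames <- stage("dark", subtract_dark(raw))
  frames <- stage("despike", remove_cosmic_rays(frames, params$despike_threshold))
  axis <- stage("calibrate",
                calibrate_axis(calib, raw$axis_pixels, params$calib_poly_degree))
  frames <- stage("response", correct_response(frames, calib))
  avg <- colMeans(frames)
  bb <- stage("baseline",
              bubblefill_baseline(avg, axis$shifts, params$bubble_min_width))
  sm <- stage("smooth", smooth_sg(bb$raman, params$sg_order, params$sg_window))
  tr <- stage("truncate",
              truncate_spectrum(sm, axis$shifts, params$truncate_lo, params$truncate_hi))
  norm <- stage("snv", snv(tr$intensities))
  processed_spectrum(spectral_axis(tr$shifts, axis$nominal_resolution),
                     norm, raw$meta)
}

#' Preprocess every acquisition in a raw dataset
#'
#' @param raw_set A [raman_raw_set()].
#' @param calib A [calibration_set()].
#' @param params A [preprocess_params()].
#' @return A [raman_set()] of processed fingerprints (quality factors unset).
#' @export
preprocess_dataset <- function(raw_set,
                               calib = NULL,
                               params = preprocess_params()) {
  stopifnot(inherits(raw_set, "raman_raw_set"))
  if (!length(raw_set$acquisitions))
    abort_structural("raw dataset is empty")
  if (is.null(calib))
    calib <- default_calibration(raw_set$acquisitions[[1]]$axis_pixels)
  specs <- lapply(raw_set$acquisitions, preprocess, calib = calib, params = params)
  axis <- specs[[1]]$axis
  spectra <- do.call(rbind, lapply(specs, function(s) s$intensities))
  meta <- do.call(rbind, lapply(specs, function(s) meta_as_row(s$meta)))
  raman_set(axis, spectra, meta, provenance = raw_set$provenance)
}
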