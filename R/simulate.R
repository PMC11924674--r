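#' Synthetic acquisition generator configuration
#'
#' Defines the statistical structure of the emulated dataset: six heads,
#' nine tissues, ten accumulation frames per record, a broad autofluorescence
#' baseline, shot-like noise, sporadic cosmic-ray spikes, per-head band
#' random effects, and three gland preparation methods whose record-level
#' variability is strictly ordered `in_situ > ex_situ > in_section`.
#'
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of (seed, config).
#' @param n_heads Number of subjects (default 6).
#' @param records_per_tissue_per_head Replicates per (head, tissue, prep)
#'   cell (default 5; with 9 tissues and 6 heads this matches the ~280-record
#'   scale of a measurement session).
#' @param head_effect_sd Log-sd of the per-(head, band) multiplicative
#'   amplitude effect (default 0.03).
#' @param record_jitter_sd Log-sd of the per-record, per-band amplitude
#'   jitter before the preparation multiplier (default 0.08).
#' @param cosmic_ray_rate Expected cosmic-ray spikes per accumulation frame
#'   (default 0.05).
#' @param prep_variance_multipliers Named positive scales applied to
#'   record-level variability for the three gland preparation methods; must be
#'   strictly ordered `in_situ > ex_situ > in_section`.
#' @param prep_contamination Named mean mixing fractions of surrounding-tissue
#'   (sella dura) signal in gland records per preparation method. In-place
#'   measurements pick up the most bleed-through from neighbouring structures,
#'   sectioned glands the least.
#' @param contamination_sd Gaussian sd of the per-record bone-mixing jitter in
#'   sella dura records (default 0.04; fractions are clamped to `[0, 1]`).
#' @param prep_contamination_sd Gaussian sd of the per-record
#'   surrounding-tissue mixing jitter in gland records, scaled by the
#'   preparation multiplier (default 0.04). Together with the method scaling
#'   of noise and band jitter this drives the preparation-method variance
#'   ordering.
#' @param baseline_jitter_sd Log-sd of per-record baseline amplitude jitter.
#' @param dark_level Mean dark counts per pixel (default 100).
#' @param n_pixels Detector pixels (default 1601, ~1 cm-1 bin spacing).
#' @param shift_range True axis span in cm-1 (default 400-2000).
#' @param n_accumulations Frames per record (default 10).
#' @param saturation CCD ceiling in counts.
#' @param prep_heads Head ids used for the ex-situ / in-section gland
#'   experiment (default the first three heads).
#' @param gland_prep_methods If `TRUE` (default) the gland is additionally
#'   emitted under `ex_situ` and `in_section` preparation on `prep_heads`.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_heads = 6L,
                             records_per_tissue_per_head = 5L,
                             head_effect_sd = 0.03,
                             record_jitter_sd = 0.08,
                             cosmic_ray_rate = 0.05,
                             prep_variance_multipliers =
                               c(in_situ = 1, ex_situ = 0.6, in_section = 0.3),
                             prep_contamination =
                               c(in_situ = 0.15, ex_situ = 0.06, in_section = 0.01),
                             contamination_sd = 0.04,
                             prep_contamination_sd = 0.04,
                             baseline_jitter_sd = 0.15,
                             dark_level = 100,
                             n_pixels = 1601L,
                             shift_range = c(400, 2000),
                             n_accumulations = 10L,
                             saturation = 65535,
                             prep_heads = NULL,
                             gland_prep_methods = TRUE) {
  m <- prep_variance_multipliers
  if (!all(RAMAN_PREP_METHODS %in% names(m)))
    abort_config("prep_variance_multipliers must name in_situ, ex_situ and in_section")
  if (any(m <= 0))
    abort_config("prep_variance_multipliers must be positive")
  if (!(m[["in_situ"]] > m[["ex_situ"]] && m[["ex_situ"]] > m[["in_section"]]))
    abort_config("prep_variance_multipliers must be strictly ordered in_situ > ex_situ > in_section")
  if (!all(RAMAN_PREP_METHODS %in% names(prep_contamination)))
    abort_config("prep_contamination must name all three preparation methods")
  if (n_heads < 1 || records_per_tissue_per_head < 1)
    abort_config("n_heads and records_per_tissue_per_head must be >= 1")
  if (is.null(prep_heads)) prep_heads <- seq_len(min(3L, n_heads))
  structure(list(seed = as.integer(seed), n_heads = as.integer(n_heads),
                 records_per_tissue_per_head = as.integer(records_per_tissue_per_head),
                 head_effect_sd = head_effect_sd,
                 record_jitter_sd = record_jitter_sd,
                 cosmic_ray_rate = cosmic_ray_rate,
                 prep_variance_multipliers = m[RAMAN_PREP_METHODS],
                 prep_contamination = prep_contamination[RAMAN_PREP_METHODS],
                 contamination_sd = contamination_sd,
                 prep_contamination_sd = prep_contamination_sd,
                 baseline_jitter_sd = baseline_jitter_sd,
                 dark_level = dark_level,
                 n_pixels = as.integer(n_pixels),
                 shift_range = as.numeric(shift_range),
                 n_accumulations = as.integer(n_accumulations),
                 saturation = saturation,
                 prep_heads = as.integer(prep_heads),
                 gland_prep_methods = isTRUE(gland_prep_methods)),
            class = "generator_config")
}

# Protocol exposure times (s): brain tissue needs the longest integration.
exposure_defaults <- c(pituitary_gland = 5, optic_chiasm = 6, st_bone = 4,
                       st_dura = 4.5, sphenoid_bone = 4.5, nasal_septum = 4,
                       nasal_mucosa = 5, white_matter = 8.9, gray_matter = 10.1)

# Deterministic mean signal (band peaks only, no baseline/noise) of a profile
# given per-band multiplicative factors.
profile_signal <- function(profile, shifts, factors = 1) {
  b <- profile$bands
  amps <- profile$amplitude_unit * b$relative_intensity * factors
  sig <- numeric(length(shifts))
  for (j in seq_len(nrow(b)))
    sig <- sig + amps[j] * pseudo_voigt(shifts, b$center[j], b$fwhm[j])
  sig
}

#' Expected noise-free signal of a synthetic tissue
#'
#' Closed-form evaluation of the generator's mean function (dark + baseline +
#' peak sum, including the profile's contamination mixture) on the true axis.
#' Used as the oracle for preprocessing-recovery tests.
#'
#' @param profile A `tissue_profile`.
#' @param config A [generator_config()].
#' @param profiles Profile map (needed to resolve contamination mixtures).
#' @return List with `shifts`, `peaks` (Raman signal only), `baseline`, and
#'   `total` (dark + baseline + peaks).
#' @export
expected_signal <- function(profile, config = generator_config(),
                            profiles = default_profiles()) {
  shifts <- seq(config$shift_range[1], config$shift_range[2],
                length.out = config$n_pixels)
  peaks <- profile_signal(profile, shifts)
  if (!is.null(profile$contamination)) {
    other <- profiles[[profile$contamination$tissue]]
    f <- profile$contamination$fraction
    peaks <- (1 - f) * peaks + f * profile_signal(other, shifts)
  }
  baseline <- profile$baseline_amplitude * baseline_curve(profile$baseline_shape, shifts)
  list(shifts = shifts, peaks = peaks, baseline = baseline,
       total = config$dark_level + baseline + peaks)
}

#' Generate a labelled synthetic raw dataset
#'
#' Emulates a probe measurement session: for every (head, tissue, replicate)
#' cell it emits `n_accumulations` CCD frames equal to dark counts + broad
#' autofluorescence baseline + pseudo-Voigt band peaks, with per-head and
#' per-record multiplicative band jitter, shot-like heteroscedastic noise and
#' Poisson cosmic-ray spikes. The pituitary gland is additionally emitted
#' under the ex-situ and in-section preparation methods (on `prep_heads`) with
#' method-scaled variability and method-dependent bleed-through of
#' surrounding-tissue signal. Output is a deterministic function of
#' (seed, config, profiles).
#'
#' @param config A [generator_config()].
#' @param profiles Profile map as from [default_profiles()]; generate a
#'   subset of tissues by passing a subset of profiles.
#' @return A [raman_raw_set()].
#' @export
generate_raw <- function(config = generator_config(),
                         profiles = default_profiles()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  shifts <- seq(config$shift_range[1], config$shift_range[2],
                length.out = config$n_pixels)
  np <- config$n_pixels
  tissues <- intersect(RAMAN_TISSUES, names(profiles))
  if (!length(tissues)) abort_config("profiles must cover at least one known tissue")

  # Per-(head, tissue, band) multiplicative log-normal effects, drawn in a
  # fixed order so the dataset is reproducible.
  head_fx <- lapply(seq_len(config$n_heads), function(h) {
    fx <- lapply(tissues, function(tis)
      stats::rlnorm(nrow(profiles[[tis]]$bands), 0, config$head_effect_sd))
    names(fx) <- tissues
    fx
  })

  unit_baseline <- lapply(tissues, function(tis)
    baseline_curve(profiles[[tis]]$baseline_shape, shifts))
  names(unit_baseline) <- tissues

  # Contaminant profiles for mixtures (falling back to the reference registry
  # when the contaminating tissue is not among the generated profiles).
  contaminant_prof <- lapply(tissues, function(tis) {
    ct <- profiles[[tis]]$contamination
    if (is.null(ct)) return(NULL)
    if (ct$tissue %in% tissues) profiles[[ct$tissue]] else
      default_profiles(amplitude_unit = profiles[[tis]]$amplitude_unit)[[ct$tissue]]
  })
  names(contaminant_prof) <- tissues

  # Fixed surrounding-tissue contaminant for gland records: the overlying
  # sella dura (which itself carries its bone component).
  gland_contaminant <- NULL
  if ("pituitary_gland" %in% tissues) {
    au <- profiles[["pituitary_gland"]]$amplitude_unit
    ref <- default_profiles(amplitude_unit = au)
    dsig <- profile_signal(ref$st_dura, shifts)
    bf <- ref$st_dura$contamination$fraction
    gland_contaminant <- (1 - bf) * dsig +
      bf * profile_signal(ref$st_bone, shifts)
  }

  make_record <- function(head, tis, prep, repl) {
    prof <- profiles[[tis]]
    m <- config$prep_variance_multipliers[[prep]]
    jit <- stats::rlnorm(nrow(prof$bands), 0, config$record_jitter_sd * m)
    sig <- profile_signal(prof, shifts, head_fx[[head]][[tis]] * jit)

    if (!is.null(prof$contamination)) {
      other <- prof$contamination$tissue
      f <- min(max(prof$contamination$fraction +
                     stats::rnorm(1, 0, config$contamination_sd), 0), 1)
      ofac <- if (other %in% tissues) head_fx[[head]][[other]] else 1
      sig <- (1 - f) * sig + f * profile_signal(contaminant_prof[[tis]], shifts, ofac)
    }
    if (tis == "pituitary_gland") {
      # Method-dependent bleed-through of the overlying dura (which itself
      # carries a bone component): largest in place, smallest in section.
      g <- min(max(config$prep_contamination[[prep]] +
                     stats::rnorm(1, 0, config$prep_contamination_sd * m), 0), 1)
      if (g > 0) sig <- (1 - g) * sig + g * gland_contaminant
    }

    bl <- prof$baseline_amplitude *
      stats::rlnorm(1, 0, config$baseline_jitter_sd) * unit_baseline[[tis]]
    mu <- config$dark_level + bl + sig
    # the preparation multiplier scales every record-level stochastic
    # component: band jitter, mixing jitter and effective measurement noise
    sd <- prof$noise_scale * m * sqrt(mu)
    frames <- matrix(0, config$n_accumulations, np)
    for (a in seq_len(config$n_accumulations)) {
      fr <- mu + stats::rnorm(np, 0, sd)
      if (config$cosmic_ray_rate > 0) {
        nsp <- stats::rpois(1, config$cosmic_ray_rate)
        if (nsp > 0) {
          at <- sample.int(np, nsp)
          fr[at] <- fr[at] + stats::runif(nsp, 2000, 15000)
        }
      }
      frames[a, ] <- pmin(pmax(fr, 0), config$saturation)
    }
    dark <- pmin(pmax(config$dark_level +
                        stats::rnorm(np, 0, prof$noise_scale * sqrt(config$dark_level)),
                      0), config$saturation)
    expo <- min(max(exposure_defaults[[tis]] + stats::runif(1, -0.5, 0.5), 3), 11)
    raw_acquisition(frames, dark,
                    acquisition_meta(head, tis, prep, expo, 40, repl),
                    saturation = config$saturation)
  }

  acqs <- list()
  for (head in seq_len(config$n_heads)) {
    for (tis in tissues) {
      preps <- "in_situ"
      if (tis == "pituitary_gland" && config$gland_prep_methods &&
          head %in% config$prep_heads)
        preps <- RAMAN_PREP_METHODS
      for (prep in preps)
        for (repl in seq_len(config$records_per_tissue_per_head))
          acqs[[length(acqs) + 1L]] <- make_record(head, tis, prep, repl)
    }
  }
  raman_raw_set(acqs, provenance = list(seed = config$seed,
                                        config = unclass(config)))
}
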