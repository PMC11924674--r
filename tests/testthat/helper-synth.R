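# Shared fixtures for the test suite; everything is generated in code.

# Small, fast generator configuration for unit tests (coarser 4 cm-1 grid);
# any field can be overridden.
tiny_config <- function(...) {
  args <- utils::modifyList(list(seed = 1, n_heads = 3,
                                 records_per_tissue_per_head = 2,
                                 n_pixels = 401, gland_prep_methods = FALSE),
                            list(...))
  do.call(generator_config, args)
}

# A noiseless configuration: frames equal the generator's mean function.
noise_free_config <- function(...) {
  args <- utils::modifyList(list(seed = 1, head_effect_sd = 0,
                                 record_jitter_sd = 0, cosmic_ray_rate = 0,
                                 contamination_sd = 0, prep_contamination_sd = 0,
                                 baseline_jitter_sd = 0,
                                 prep_contamination = c(in_situ = 0, ex_situ = 0,
                                                        in_section = 0)),
                            list(...))
  do.call(generator_config, args)
}

# Unit-height pseudo-Voigt matching the generator's peak shape.
pv_peak <- function(x, center, fwhm, eta = 0.5) {
  g <- fwhm / 2
  eta * g^2 / ((x - center)^2 + g^2) +
    (1 - eta) * exp(-4 * log(2) * (x - center)^2 / fwhm^2)
}

# Build a processed raman_set directly from a matrix of raw intensity rows
# (rows are SNV-normalized here), bypassing the preprocessing chain.
make_snv_set <- function(rows, tissue, head_id, prep_method = "in_situ",
                         shifts = seq(800, 1800, length.out = ncol(rows))) {
  rows <- t(apply(rows, 1, snv))
  idx <- stats::ave(seq_along(tissue),
                    paste(head_id, tissue, prep_method), FUN = seq_along)
  meta <- data.frame(head_id = as.integer(head_id), tissue = tissue,
                     prep_method = prep_method, replicate = as.integer(idx),
                     exposure_time_s = 5, laser_power_mw = 40, qf = NA_real_,
                     stringsAsFactors = FALSE)
  raman_set(spectral_axis(shifts), rows, meta)
}

# Two-class spectra that differ only at one planted band.
planted_band_set <- function(n_per_class = 20, center = 1300, amp = 4,
                             shifts = seq(800, 1800, by = 2), sd = 1,
                             seed = 1) {
  set.seed(seed)
  nb <- length(shifts)
  base <- 2 * pv_peak(shifts, 1004, 15) + 3 * pv_peak(shifts, 1650, 15)
  rows <- matrix(rnorm(2 * n_per_class * nb, sd = sd), ncol = nb)
  rows <- rows + matrix(base, 2 * n_per_class, nb, byrow = TRUE)
  cls2 <- seq_len(n_per_class) + n_per_class
  rows[cls2, ] <- rows[cls2, ] +
    matrix(amp * pv_peak(shifts, center, 15), n_per_class, nb, byrow = TRUE)
  list(x = rows, y = rep(c("a", "b"), each = n_per_class), shifts = shifts)
}
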