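# Shared fixtures, all generated in code.

# Instrument with every stochastic term switched off: spectra are the exact
# linear band mixture.
quiet_instrument <- function(band_library = default_band_library()) {
  instrument_model(band_library = band_library, baseline_order = 0,
                   scatter_gain_sd = 0, scatter_offset_sd = 0, noise_sd = 0)
}

# Scatter only (gain/offset), no additive noise or baseline: SNV should make
# replicates of one sample identical.
scatter_instrument <- function(gain_sd = 0.2, offset_sd = 0.05) {
  instrument_model(baseline_order = 0, scatter_gain_sd = gain_sd,
                   scatter_offset_sd = offset_sd, noise_sd = 0)
}

# SH-only instrument with both analyte bands planted inside intervals 2 and 7
# of a 10-interval partition of 256 channels (1018-1180 nm and 1859-2015 nm),
# moderate noise, no scatter. Used for interval-recovery checks.
planted_instrument <- function() {
  bl <- rbind(
    band(1100, 15, "SH", 0.010),
    band(1935, 15, "SH", 0.010)
  )
  instrument_model(band_library = bl, baseline_order = 2,
                   baseline_amp_sd = 0.005, scatter_gain_sd = 0,
                   scatter_offset_sd = 0, noise_sd = 0.003)
}

# Strongly saturating SS response: half-saturation constant well below the
# simulated SS range (everything operates in the saturated regime), with the
# SS band gains scaled up so the saturated signal still spans an absorbance
# range comparable to the linear instrument.
saturating_instrument <- function() {
  bl <- default_band_library()
  bl$loading[bl$analyte == "SS"] <- bl$loading[bl$analyte == "SS"] * 20
  instrument_model(band_library = bl, nonlinear_ss_saturation = 12)
}

# Small random regression problem with a planted latent dimension.
make_latent_data <- function(n, p, dim, noise_sd, seed) {
  withr::with_seed(seed, {
    scores <- matrix(rnorm(n * dim), n, dim)
    load <- matrix(rnorm(dim * p), dim, p)
    X <- scores %*% load + matrix(rnorm(n * p, 0, noise_sd), n, p)
    y <- as.numeric(scores %*% seq_len(dim)) + rnorm(n, 0, noise_sd)
    list(X = X, y = y)
  })
}

# Simulate, average replicates and (optionally) preprocess a dataset for one
# target. Planted-band fixtures have no scatter, so they are modelled on the
# raw absorbances.
simulate_cal_pred <- function(instrument, seed, target = "SH",
                              design = experiment_design(),
                              preprocess = c("snv", "none")) {
  preprocess <- match.arg(preprocess)
  refs <- simulate_reference_trajectories(design, seed = seed)
  spectra <- simulate_spectra(refs, instrument,
                              replicates = design$replicates_per_sample,
                              seed = seed + 1L)
  ds <- build_dataset(spectra, refs)
  split <- split_one_in_three(ds$meta$sample_id)
  Xp <- if (preprocess == "snv") snv(ds$X) else ds$X
  y <- if (target == "SH") ds$y_SH else ds$y_SS
  list(x_cal = Xp[split$cal_idx, , drop = FALSE],
       y_cal = y[split$cal_idx],
       x_pred = Xp[split$pred_idx, , drop = FALSE],
       y_pred = y[split$pred_idx],
       wavelengths = ds$wavelengths, split = split, dataset = ds)
}
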