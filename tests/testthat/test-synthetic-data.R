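test_that("default design yields the protocol bookkeeping", {
  d <- experiment_design()
  refs <- simulate_reference_trajectories(d, seed = 11)
  expect_equal(nrow(refs), 64)
  expect_equal(n_samples(d), 64)
  key <- paste(refs$power_density_W_per_L, refs$time_min)
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(refs$SH_umol_g > 0) && all(refs$SS_umol_g > 0))

  sp <- simulate_spectra(refs, instrument_model(), replicates = 3, seed = 12)
  expect_equal(dim(sp$absorbance), c(192, 256))
  expect_true(all(table(sp$sample_id) == 3))
  expect_true(all(diff(sp$wavelengths) > 0))
  expect_false(anyNA(sp$absorbance))
})

test_that("zero amplitude and zero noise give constant trajectories", {
  p <- trajectory_params(sh_amp0 = 0, sh_amp_slope = 0, sh_noise_sd = 0,
                         ss_amp0 = 0, ss_amp_slope = 0, ss_noise_sd = 0)
  refs <- simulate_reference_trajectories(experiment_design(), p, seed = 3)
  for (d in unique(refs$power_density_W_per_L)) {
    sub <- refs[refs$power_density_W_per_L == d, ]
    expect_equal(var(sub$SH_umol_g), 0)
    expect_equal(var(sub$SS_umol_g), 0)
  }
})

test_that("fluctuation intensity is monotone in power density", {
  d <- experiment_design(power_densities = c(0, 160))
  refs <- simulate_reference_trajectories(d, seed = 42)
  v <- tapply(refs$SH_umol_g, refs$power_density_W_per_L, var)
  expect_gt(v[["160"]], v[["0"]])
  v_ss <- tapply(refs$SS_umol_g, refs$power_density_W_per_L, var)
  expect_gt(v_ss[["160"]], v_ss[["0"]])
})

test_that("invalid designs and parameters are rejected", {
  expect_error(experiment_design(duration_min = 30, sampling_interval_min = 7),
               "design error")
  expect_error(experiment_design(replicates_per_sample = 0), "design error")
  expect_error(experiment_design(power_densities = c(-10, 80)), "design error")
  expect_error(trajectory_params(sh_amp0 = -1), "parameter error")
  expect_error(instrument_model(n_channels = 1), "parameter error")
  expect_error(instrument_model(lambda_min = 2500, lambda_max = 850),
               "parameter error")
  refs <- simulate_reference_trajectories(experiment_design(), seed = 1)
  no_analyte <- instrument_model(
    band_library = band(970, 60, "interferent", 0.2))
  expect_error(simulate_spectra(refs, no_analyte, seed = 1),
               "configuration error")
})

test_that("noiseless spectra equal the exact band mixture", {
  refs <- simulate_reference_trajectories(experiment_design(), seed = 7)
  inst <- quiet_instrument()
  sp <- simulate_spectra(refs, inst, replicates = 2, seed = 8)
  lambda <- wavelength_grid(inst)
  bl <- inst$band_library
  mix <- function(sh, ss) {
    out <- numeric(length(lambda))
    for (i in seq_len(nrow(bl))) {
      conc <- switch(bl$analyte[i], SH = sh, SS = ss, interferent = 1)
      out <- out + conc * bl$loading[i] *
        exp(-0.5 * ((lambda - bl$center_nm[i]) / bl$width_nm[i])^2)
    }
    out
  }
  for (i in c(1, 40, 128)) {
    ref_row <- refs[match(sp$sample_id[i], refs$sample_id), ]
    expect_equal(sp$absorbance[i, ],
                 mix(ref_row$SH_umol_g, ref_row$SS_umol_g),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("SNV cancels per-spectrum gain and offset exactly", {
  refs <- simulate_reference_trajectories(experiment_design(), seed = 5)
  sp <- simulate_spectra(refs, scatter_instrument(), replicates = 3, seed = 6)
  rows <- which(sp$sample_id == sp$sample_id[1])
  z <- snv(sp$absorbance[rows, ])
  expect_lt(max(abs(z[1, ] - z[2, ])), 1e-8)
  expect_lt(max(abs(z[1, ] - z[3, ])), 1e-8)
})

test_that("identical seeds reproduce tables and matrices bit-for-bit", {
  d <- experiment_design()
  r1 <- simulate_reference_trajectories(d, seed = 99)
  r2 <- simulate_reference_trajectories(d, seed = 99)
  expect_identical(r1, r2)
  s1 <- simulate_spectra(r1, instrument_model(), replicates = 3, seed = 100)
  s2 <- simulate_spectra(r2, instrument_model(), replicates = 3, seed = 100)
  expect_identical(s1, s2)
  r3 <- simulate_reference_trajectories(d, seed = 98)
  expect_false(identical(r1, r3))
})

test_that("full-spectrum PLS recovers SH exactly on noiseless data", {
  p <- trajectory_params(sh_noise_sd = 0, ss_noise_sd = 0)
  refs <- simulate_reference_trajectories(experiment_design(), p, seed = 21)
  sp <- simulate_spectra(refs, quiet_instrument(), replicates = 1, seed = 22)
  ds <- build_dataset(sp, refs)
  m <- fit_pls(ds$X, ds$y_SH, 2)
  expect_equal(cor(m$fitted, ds$y_SH), 1, tolerance = 1e-8)
  expect_lt(sqrt(mean((m$fitted - ds$y_SH)^2)), 1e-8)
})
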