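#' Trajectory model parameters for SH and SS reference values
#'
#' The reference chemistry is modelled as a baseline plus a power-dependent
#' damped oscillation plus white noise:
#' `c(d, t) = baseline + drift * d + amp(d) * exp(-damping * t) *
#' sin(2 * pi * t / period + phase) + eps`, with
#' `amp(d) = amp0 + amp_slope * d` non-decreasing in the power density `d`
#' (the stronger the ultrasound, the more intense the fluctuation) and one
#' random phase per (power density, analyte). Defaults keep SH within about
#' 1.95-5.42 umol/g and SS within about 32.3-75.4 umol/g, the ranges observed
#' for wheat gluten; ultrasound raises SH (positive drift) and lowers SS
#' (negative drift) relative to the stirred control.
#'
#' @param sh_baseline,ss_baseline Mean level at 0 W/L (umol/g).
#' @param sh_drift,ss_drift Level shift per W/L (umol/g per W/L).
#' @param sh_amp0,ss_amp0 Oscillation amplitude at 0 W/L (umol/g, >= 0).
#' @param sh_amp_slope,ss_amp_slope Amplitude increase per W/L (>= 0).
#' @param sh_period_min,ss_period_min Oscillation period (min).
#' @param sh_damping,ss_damping Exponential damping rate (1/min).
#' @param sh_noise_sd,ss_noise_sd SD of additive white noise (umol/g).
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(sh_baseline = 3.6, sh_drift = 0.0015,
                              sh_amp0 = 0.25, sh_amp_slope = (1.2 - 0.25) / 160,
                              sh_period_min = 12, sh_damping = 0.02,
                              sh_noise_sd = 0.08,
                              ss_baseline = 52, ss_drift = -0.03,
                              ss_amp0 = 2.5, ss_amp_slope = (12 - 2.5) / 160,
                              ss_period_min = 10, ss_damping = 0.02,
                              ss_noise_sd = 0.9) {
  p <- list(sh_baseline = sh_baseline, sh_drift = sh_drift, sh_amp0 = sh_amp0,
            sh_amp_slope = sh_amp_slope, sh_period_min = sh_period_min,
            sh_damping = sh_damping, sh_noise_sd = sh_noise_sd,
            ss_baseline = ss_baseline, ss_drift = ss_drift, ss_amp0 = ss_amp0,
            ss_amp_slope = ss_amp_slope, ss_period_min = ss_period_min,
            ss_damping = ss_damping, ss_noise_sd = ss_noise_sd)
  if (p$sh_amp0 < 0 || p$ss_amp0 < 0 || p$sh_amp_slope < 0 ||
      p$ss_amp_slope < 0) {
    stop("parameter error: oscillation amplitudes must be non-negative")
  }
  if (p$sh_noise_sd < 0 || p$ss_noise_sd < 0) {
    stop("parameter error: noise standard deviations must be >= 0")
  }
  if (p$sh_period_min <= 0 || p$ss_period_min <= 0) {
    stop("parameter error: oscillation periods must be > 0")
  }
  structure(p, class = "trajectory_params")
}

#' Simulate SH/SS reference trajectories
#'
#' Generates one reference-chemistry row per (power density, timepoint) of
#' the design, following the baseline + damped-oscillation + noise model of
#' [trajectory_params()]. Rows are ordered by power density, then time, the
#' canonical order assumed by [split_one_in_three()].
#'
#' @param design An [experiment_design()].
#' @param params A [trajectory_params()].
#' @param seed Integer seed; identical seeds reproduce identical tables.
#' @return A `reference_table` data frame with columns `sample_id`,
#'   `power_density_W_per_L`, `time_min`, `SH_umol_g`, `SS_umol_g`.
#' @examples
#' refs <- simulate_reference_trajectories(experiment_design(), seed = 1)
#' nrow(refs) # 64
#' @export
simulate_reference_trajectories <- function(design,
                                            params = trajectory_params(),
                                            seed) {
  stopifnot(inherits(design, "experiment_design"))
  if (!inherits(params, "trajectory_params")) {
    params <- do.call(trajectory_params, params)
  }
  if (missing(seed)) stop("seed is required")
  tt <- timepoints(design)
  withr::with_seed(as.integer(seed), {
    rows <- lapply(design$power_densities, function(d) {
      phase_sh <- runif(1, 0, 2 * pi)
      phase_ss <- runif(1, 0, 2 * pi)
      sh <- params$sh_baseline + params$sh_drift * d +
        (params$sh_amp0 + params$sh_amp_slope * d) *
          exp(-params$sh_damping * tt) *
          sin(2 * pi * tt / params$sh_period_min + phase_sh) +
        rnorm(length(tt), 0, params$sh_noise_sd)
      ss <- params$ss_baseline + params$ss_drift * d +
        (params$ss_amp0 + params$ss_amp_slope * d) *
          exp(-params$ss_damping * tt) *
          sin(2 * pi * tt / params$ss_period_min + phase_ss) +
        rnorm(length(tt), 0, params$ss_noise_sd)
      data.frame(
        sample_id = sprintf("d%03.0f_t%05.1f", d, tt),
        power_density_W_per_L = d,
        time_min = tt,
        SH_umol_g = sh,
        SS_umol_g = ss,
        stringsAsFactors = FALSE
      )
    })
    refs <- do.call(rbind, rows)
    rownames(refs) <- NULL
    if (any(refs$SH_umol_g <= 0) || any(refs$SS_umol_g <= 0)) {
      stop("parameter error: trajectory parameters produced non-positive concentrations")
    }
    class(refs) <- c("reference_table", "data.frame")
    refs
  })
}

gaussian_band <- function(lambda, center, width) {
  exp(-0.5 * ((lambda - center) / width)^2)
}

pure_component_spectrum <- function(lambda, bands) {
  if (nrow(bands) == 0) return(numeric(length(lambda)))
  out <- numeric(length(lambda))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$loading[i] *
      gaussian_band(lambda, bands$center_nm[i], bands$width_nm[i])
  }
  out
}

#' Simulate NIR spectra for a reference table
#'
#' Each replicate spectrum is
#' `gain * (SH * g_SH + f(SS) * g_SS + interferents + baseline) + offset +
#' noise`, where `g_SH`/`g_SS` are the pure-component band mixtures of the
#' instrument's band library, `f` is the (optionally saturating) SS response,
#' the baseline is a random polynomial drift, and gain/offset emulate
#' multiplicative and additive scatter. With all noise terms zero the
#' spectrum is exactly the linear band mixture.
#'
#' @param refs A `reference_table` from [simulate_reference_trajectories()].
#' @param instrument An [instrument_model()].
#' @param replicates Replicate spectra per sample (>= 1).
#' @param seed Integer seed; identical seeds reproduce identical matrices.
#' @return A `spectra_set`: list with `wavelengths`, `absorbance`
#'   (n_spectra x n_channels matrix), `sample_id`, `replicate`.
#' @export
simulate_spectra <- function(refs, instrument = instrument_model(),
                             replicates = 3, seed) {
  stopifnot(inherits(refs, "data.frame"))
  if (nrow(refs) == 0) stop("refs must be non-empty")
  stopifnot(inherits(instrument, "instrument_model"))
  if (missing(seed)) stop("seed is required")
  if (replicates < 1) stop("design error: replicates must be >= 1")
  bl <- instrument$band_library
  if (nrow(bl) == 0 || !any(bl$analyte %in% c("SH", "SS"))) {
    stop("configuration error: band library has no analyte bands")
  }
  lambda <- wavelength_grid(instrument)
  p <- instrument$n_channels
  g_sh <- pure_component_spectrum(lambda, bl[bl$analyte == "SH", , drop = FALSE])
  g_ss <- pure_component_spectrum(lambda, bl[bl$analyte == "SS", , drop = FALSE])
  g_int <- pure_component_spectrum(lambda, bl[bl$analyte == "interferent", , drop = FALSE])
  K <- instrument$nonlinear_ss_saturation
  ss_eff <- if (is.finite(K)) refs$SS_umol_g / (1 + refs$SS_umol_g / K) else refs$SS_umol_g
  u <- if (p > 1) 2 * (lambda - lambda[1]) / (lambda[p] - lambda[1]) - 1 else 0
  n_spec <- nrow(refs) * replicates
  withr::with_seed(as.integer(seed), {
    A <- matrix(0, n_spec, p)
    sample_id <- character(n_spec)
    replicate <- integer(n_spec)
    row <- 0L
    for (i in seq_len(nrow(refs))) {
      base <- refs$SH_umol_g[i] * g_sh + ss_eff[i] * g_ss + g_int
      for (r in seq_len(replicates)) {
        row <- row + 1L
        gain <- max(1 + rnorm(1, 0, instrument$scatter_gain_sd), 0.1)
        offset <- rnorm(1, 0, instrument$scatter_offset_sd)
        drift <- numeric(p)
        if (instrument$baseline_order > 0) {
          for (j in seq_len(instrument$baseline_order)) {
            drift <- drift + rnorm(1, 0, instrument$baseline_amp_sd / j) * u^j
          }
        }
        noise <- if (instrument$noise_sd > 0) rnorm(p, 0, instrument$noise_sd) else numeric(p)
        A[row, ] <- gain * (base + drift) + offset + noise
        sample_id[row] <- refs$sample_id[i]
        replicate[row] <- r
      }
    }
    rownames(A) <- sprintf("%s_r%d", sample_id, replicate)
    structure(
      list(wavelengths = lambda, absorbance = A,
           sample_id = sample_id, replicate = replicate),
      class = "spectra_set"
    )
  })
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d channels (%.1f-%.1f nm), %d samples\n",
              nrow(x$absorbance), ncol(x$absorbance),
              min(x$wavelengths), max(x$wavelengths),
              length(unique(x$sample_id))))
  invisible(x)
}
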