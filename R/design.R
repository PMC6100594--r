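#' Ultrasound monitoring experiment design
#'
#' Describes the acquisition protocol of an in-situ ultrasound run: which
#' power densities are applied, for how long, how often the suspension is
#' sampled, and how many replicate spectra are taken per sample. The default
#' reproduces the study protocol: 0/80/120/160 W/L for 30 min, a sample every
#' 2 min including time zero (16 timepoints, 64 samples), triplicate spectra
#' (192 spectra).
#'
#' @param power_densities Applied ultrasound power densities in W/L
#'   (non-negative; 0 = stirred control).
#' @param duration_min Treatment duration in minutes.
#' @param sampling_interval_min Minutes between successive samples; must
#'   divide `duration_min`.
#' @param replicates_per_sample Number of replicate spectra acquired per
#'   sample (>= 1).
#' @param include_time_zero Include a sample at t = 0 before treatment.
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design()
#' n_samples(d) # 64
#' @export
experiment_design <- function(power_densities = c(0, 80, 120, 160),
                              duration_min = 30,
                              sampling_interval_min = 2,
                              replicates_per_sample = 3,
                              include_time_zero = TRUE) {
  if (length(power_densities) < 1 || any(power_densities < 0)) {
    stop("design error: power densities must be non-negative")
  }
  if (anyDuplicated(power_densities)) {
    stop("design error: duplicated power densities")
  }
  if (duration_min <= 0 || sampling_interval_min <= 0 ||
      duration_min %% sampling_interval_min != 0) {
    stop("design error: duration must be a positive multiple of the sampling interval")
  }
  if (replicates_per_sample < 1) {
    stop("design error: replicates_per_sample must be >= 1")
  }
  structure(
    list(
      power_densities = as.numeric(sort(power_densities)),
      duration_min = as.numeric(duration_min),
      sampling_interval_min = as.numeric(sampling_interval_min),
      replicates_per_sample = as.integer(replicates_per_sample),
      include_time_zero = isTRUE(include_time_zero)
    ),
    class = "experiment_design"
  )
}

#' Sampling timepoints of a design
#' @param design An [experiment_design()].
#' @return Numeric vector of sampling times in minutes.
#' @export
timepoints <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  from <- if (design$include_time_zero) 0 else design$sampling_interval_min
  seq(from, design$duration_min, by = design$sampling_interval_min)
}

#' Number of samples implied by a design
#' @param design An [experiment_design()].
#' @return Integer count of (power density, timepoint) samples.
#' @export
n_samples <- function(design) {
  length(design$power_densities) * length(timepoints(design))
}

#' Spectral band definition
#'
#' One Gaussian absorbance band. For `analyte` `"SH"` or `"SS"` the `loading`
#' is the peak absorbance contributed per umol/g of analyte; for
#' `"interferent"` it is the fixed peak absorbance of the band (water, starch
#' and other matrix absorbers that carry no analyte information).
#'
#' @param center_nm Band center wavelength (nm).
#' @param width_nm Gaussian width parameter (nm, > 0).
#' @param analyte One of `"SH"`, `"SS"`, `"interferent"`.
#' @param loading Peak absorbance per umol/g (analytes) or absolute peak
#'   absorbance (interferents).
#' @return One-row data frame; rows are stacked into a band library.
#' @export
band <- function(center_nm, width_nm, analyte, loading) {
  analyte <- match.arg(analyte, c("SH", "SS", "interferent"))
  if (width_nm <= 0) stop("parameter error: band width must be > 0")
  data.frame(center_nm = center_nm, width_nm = width_nm,
             analyte = analyte, loading = loading,
             stringsAsFactors = FALSE)
}

#' Default NIR band library
#'
#' Places SH-linked combination/overtone bands inside 869-947, 1207-1284,
#' 1458-1536 and 2205-2274 nm and SS-linked bands inside 933-992, 1388-1446,
#' 2091-2148 and 2217-2274 nm (the wavelength regions reported to track the
#' two analytes in wheat gluten), plus broad water/starch interferent bands.
#'
#' @return Data frame of bands (see [band()]).
#' @export
default_band_library <- function() {
  rbind(
    band(908,  25, "SH", 0.012),
    band(1246, 25, "SH", 0.015),
    band(1497, 25, "SH", 0.013),
    band(2240, 22, "SH", 0.010),
    band(962,  20, "SS", 0.0012),
    band(1417, 20, "SS", 0.0015),
    band(2120, 18, "SS", 0.0012),
    band(2246, 18, "SS", 0.0010),
    band(970,  60, "interferent", 0.15),
    band(1200, 80, "interferent", 0.10),
    band(1450, 70, "interferent", 0.35),
    band(1940, 80, "interferent", 0.50),
    band(2100, 60, "interferent", 0.12)
  )
}

#' NIR instrument and measurement model
#'
#' Forward model used by [simulate_spectra()]: each spectrum is
#' `gain * (analyte bands + interferent bands + polynomial baseline) +
#' offset + noise`, sampled on an equally spaced wavelength grid. The default
#' grid is 256 channels over 850-2500 nm, matching the miniature fiber-optic
#' spectrometer protocol.
#'
#' @param lambda_min,lambda_max Grid limits in nm.
#' @param n_channels Number of equally spaced channels (>= 2).
#' @param band_library Data frame of [band()] rows.
#' @param baseline_order Degree of the random per-spectrum polynomial
#'   baseline drift; 0 disables the baseline (the constant offset is carried
#'   by the scatter model instead).
#' @param baseline_amp_sd Standard deviation (absorbance) of the baseline
#'   polynomial coefficients.
#' @param scatter_gain_sd SD of the per-spectrum multiplicative scatter gain
#'   around 1.
#' @param scatter_offset_sd SD of the per-spectrum additive offset.
#' @param noise_sd SD of white instrument noise per channel (absorbance).
#' @param nonlinear_ss_saturation Half-saturation constant (umol/g) of a
#'   Michaelis-type saturating SS spectral response,
#'   `c_eff = c / (1 + c / K)`; `Inf` (default) keeps the response linear.
#'   NIR is weakly sensitive to S-S stretching, which makes the SS-spectrum
#'   relation the more nonlinear of the two; this knob emulates that.
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(lambda_min = 850, lambda_max = 2500,
                             n_channels = 256,
                             band_library = default_band_library(),
                             baseline_order = 2,
                             baseline_amp_sd = 0.01,
                             scatter_gain_sd = 0.05,
                             scatter_offset_sd = 0.01,
                             noise_sd = 0.002,
                             nonlinear_ss_saturation = Inf) {
  if (lambda_min >= lambda_max) stop("parameter error: lambda_min must be < lambda_max")
  if (n_channels < 2) stop("parameter error: n_channels must be >= 2")
  if (nrow(band_library) > 0 && any(band_library$width_nm <= 0)) {
    stop("parameter error: band widths must be > 0")
  }
  if (noise_sd < 0 || scatter_gain_sd < 0 || scatter_offset_sd < 0 ||
      baseline_amp_sd < 0) {
    stop("parameter error: noise/scatter standard deviations must be >= 0")
  }
  if (baseline_order < 0) stop("parameter error: baseline_order must be >= 0")
  if (nonlinear_ss_saturation <= 0) {
    stop("parameter error: saturation constant must be > 0 (Inf disables)")
  }
  structure(
    list(
      lambda_min = lambda_min, lambda_max = lambda_max,
      n_channels = as.integer(n_channels),
      band_library = band_library,
      baseline_order = as.integer(baseline_order),
      baseline_amp_sd = baseline_amp_sd,
      scatter_gain_sd = scatter_gain_sd,
      scatter_offset_sd = scatter_offset_sd,
      noise_sd = noise_sd,
      nonlinear_ss_saturation = nonlinear_ss_saturation
    ),
    class = "instrument_model"
  )
}

#' Wavelength grid of an instrument
#' @param instrument An [instrument_model()].
#' @return Numeric vector of `n_channels` equally spaced wavelengths (nm).
#' @export
wavelength_grid <- function(instrument) {
  stopifnot(inherits(instrument, "instrument_model"))
  seq(instrument$lambda_min, instrument$lambda_max,
      length.out = instrument$n_channels)
}

#' Read an experiment design from a YAML or JSON config file
#' @param path Config file (`.yaml`/`.yml` or `.json`) whose keys match the
#'   arguments of [experiment_design()].
#' @return An `experiment_design`.
#' @export
read_design <- function(path) {
  do.call(experiment_design, read_config(path))
}

#' Read an instrument model from a YAML or JSON config file
#'
#' Keys match the arguments of [instrument_model()]; `band_library` may be
#' given as a list of `{center_nm, width_nm, analyte, loading}` records.
#' @param path Config file path.
#' @return An `instrument_model`.
#' @export
read_instrument <- function(path) {
  cfg <- read_config(path)
  if (!is.null(cfg$band_library) && !is.data.frame(cfg$band_library)) {
    cfg$band_library <- do.call(rbind, lapply(cfg$band_library, function(b) {
      band(b$center_nm, b$width_nm, b$analyte, b$loading)
    }))
  }
  if (!is.null(cfg$nonlinear_ss_saturation) &&
      identical(cfg$nonlinear_ss_saturation, "Inf")) {
    cfg$nonlinear_ss_saturation <- Inf
  }
  do.call(instrument_model, cfg)
}

read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
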