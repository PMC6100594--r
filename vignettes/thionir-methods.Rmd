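---
title: "Models and design choices in thionir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in thionir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thionir` calibrates NIR spectra against free sulfhydryl (SH) and disulfide
(SS) content of wheat gluten sampled during ultrasound treatment. This
vignette documents the models the package implements, the tunable
parameters that matter, and the choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The synthetic study design

Real in-situ spectra for this system are not publicly available, so the
package's data module generates them. The emulated protocol is fixed by the
defaults of `experiment_design()`: four power densities (0, 80, 120,
160 W/L), 30 min of treatment, a sample every 2 min *including t = 0* (16
timepoints, hence 4 × 16 = 64 samples), and triplicate spectra per sample
(192 spectra). The instrument grid is 256 equally spaced channels over
850–2500 nm (spacing ≈ 6.47 nm).

### Reference trajectories

SH and SS references follow, per power density $d$ and time $t$,

$$c(d, t) = c_0 + \beta d + \big(a_0 + a_1 d\big)\, e^{-\gamma t}
\sin\!\left(\tfrac{2\pi t}{T} + \varphi_d\right) + \varepsilon,$$

the simplest generator producing the peak-and-trough fluctuation seen in
sonicated protein suspensions, with the oscillation amplitude
non-decreasing in power density (stronger ultrasound, stronger
fluctuation). One random phase is drawn per (density, analyte). Defaults
(`trajectory_params()`):

| parameter | SH | SS | units |
|---|---|---|---|
| baseline $c_0$ | 3.6 | 52 | µmol/g |
| drift $\beta$ | +0.0015 | −0.03 | µmol/g per W/L |
| amplitude $a_0$, $a_0 + 160 a_1$ | 0.25, 1.2 | 2.5, 12 | µmol/g |
| period $T$ | 12 | 10 | min |
| damping $\gamma$ | 0.02 | 0.02 | 1/min |
| noise SD | 0.08 | 0.9 | µmol/g |

These keep SH within roughly 1.95–5.42 µmol/g and SS within roughly
32–75 µmol/g — the ranges reported for this system — with ultrasound
raising SH and lowering SS relative to the stirred control. Positivity is
asserted, not clipped: parameter sets that would drive a concentration
non-positive are rejected.

### Spectra

Each replicate spectrum is a Beer–Lambert band mixture,

$$A(\lambda) = g \Big[\, c_{\mathrm{SH}}\, s_{\mathrm{SH}}(\lambda)
 + f(c_{\mathrm{SS}})\, s_{\mathrm{SS}}(\lambda)
 + s_{\mathrm{int}}(\lambda) + b(\lambda) \Big] + o + \epsilon(\lambda),$$

where $s_\bullet$ are sums of Gaussian bands from the instrument's band
library, $b$ is a random polynomial baseline drift, $g \sim 1 +
N(0, \sigma_g)$ and $o \sim N(0, \sigma_o)$ emulate multiplicative and
additive scatter, and $\epsilon$ is white instrument noise. The default
library places SH-linked bands inside 869–947, 1207–1284, 1458–1536 and
2205–2274 nm and SS-linked bands inside 933–992, 1388–1446, 2091–2148 and
2217–2274 nm — the wavelength regions that track the two analytes in wheat
gluten — plus broad water/starch interferent bands. SS band gains are an
order of magnitude smaller per µmol/g than SH gains, reflecting NIR's weak
sensitivity to S–S stretching.

The SS response $f$ is linear by default; setting
`nonlinear_ss_saturation = K` switches to the Michaelis form
$f(c) = c / (1 + c/K)$. Because NIR is weakly and nonlinearly sensitive to
SS, the package's "saturating instrument" configuration used in the tests
and the acceptance script sets $K = 12$ µmol/g — below the simulated SS
range, so the whole range operates in the saturated regime — and scales
the SS band gains ×20 so the saturated signal still spans an absorbance
range comparable to the linear instrument. This isolates the *shape*
nonlinearity (what a nonlinear model can exploit) from a mere loss of
sensitivity (which hurts every model equally).

### What the generator does and does not emulate

It emulates: the sampling protocol and replicate structure, band-limited
analyte information in known wavelength regions, collinear interferents,
scatter, baseline drift, white noise, and an optional nonlinear SS
response. It does **not** emulate temperature-dependent band shifts,
water-displacement effects, reference-assay bias, cavitation acoustics, or
drifts correlated across time. Synthetic runs are cleaner than the real
experiment, so the near-unity correlations seen on default settings
demonstrate correctness of the pipeline machinery, not expected
performance on instrument data.

## Preprocessing

* **SNV** centers each spectrum and scales to unit sample standard
  deviation (n−1 denominator, the convention used throughout the package).
  It removes per-spectrum gain and offset exactly, and is the pipeline
  default.
* **MSC** regresses each spectrum on a reference and corrects by the
  fitted slope/intercept. The reference is the calibration-set mean;
  prediction spectra are corrected against the *calibration* reference to
  avoid leakage. MSC is exactly idempotent only when spectra share a
  common shape; with analyte variation a second pass moves spectra by a
  quantity of second order in the signal.
* **Savitzky–Golay derivatives** default to window 11, polynomial order 2,
  derivative with respect to channel index; edges are handled by the
  polynomial fit over the first/last window so output length is preserved.

A caveat the test fixtures exposed: when spectra have *no* scatter and the
analyte bands dominate the per-spectrum variance (as in the planted-band
fixtures), SNV's normalization is itself a function of the analyte and
distorts the signal nonlinearly. Interval-recovery checks therefore run on
raw absorbances; SNV earns its place only when scatter is present, which
`compare_preprocessing()` verifies by ranking methods by full-spectrum
RMSECV.

## PLS core

`fit_pls()` is NIPALS PLS1 with X-deflation, mean-centering of X and y and
no variance scaling (SNV already normalizes spectra). Regression vectors
are accumulated for every component count up to the requested maximum, so
one fit serves the whole RMSECV curve. Numerical guards: deflation stops
when the weight or score norm underflows (effective rank reached), and
coefficient columns beyond the effective rank repeat the last valid
vector, making error curves flat rather than undefined there.

Cross-validation is leave-one-out by default — deterministic and cheap at
n ≤ ~100 — with contiguous k-fold available. Component-count ties break to
the smaller count (parsimony). The kernel (fit + fold loop) is compiled
C++ (RcppArmadillo), which is what makes the exhaustive interval search
below practical.

## Si-PLS interval search

`partition_intervals()` splits the channel axis into k contiguous
intervals whose sizes differ by at most one (the first `n mod k` intervals
take the extra channel). The search enumerates *every* combination of 2, 3
or 4 intervals for each k in 15…30, concatenates the channels, selects the
PLS component count (≤ 10) by calibration RMSECV, and ranks combinations
by that RMSECV. Prediction-set metrics are computed once per winner and
never used for selection. Ties break deterministically: fewer components,
then fewer intervals, then the lexicographically smallest index set, then
smaller k — so the winner does not depend on enumeration order. Interval
indices are reported 1-based; wavelength ranges are the first/last channel
of each interval on the instrument grid.

For the full-scale search (~221,000 combinations across k = 15…30) the
pipeline uses contiguous 5-fold cross-validation rather than leave-one-out;
at 43 calibration samples the 5-fold curve identifies the same minima at a
fraction of the fold count, and the package treats this as its standard
configuration for the exhaustive search. Direct calls to `rmsecv()` and
`select_n_components()` keep the leave-one-out default.

## BP-ANN

The network stage compresses the Si-PLS-selected channels by mean-centered
PCA and trains a three-layer network: input width = number of PCs, one
sigmoid hidden layer (default 5 units), one linear output unit. Training
is full-batch gradient descent with momentum on squared error: learning
rate 0.05, momentum 0.9, up to 2000 epochs, early stop when the loss
change drops below 1e−8. PCA scores are standardized by their training
mean/SD before entering the network so the fixed learning rate is
scale-free, and the target is mapped to [0.1, 0.9] (comfortably inside the
sigmoid's range) and unmapped on prediction. Weights initialize uniformly
in [−0.5, 0.5] from the run seed; identical seeds give bitwise-identical
networks. The input PC count is chosen by RMSECV with PCA and network
refitted per fold (contiguous 5-fold by default; per-fold seeds derive
deterministically from the run seed). Hidden width, rates and epochs are
all config-exposed (`bpann_config()`) since no single setting suits every
dataset.

## Evaluation

`split_one_in_three()` sends every third sample (positions 3, 6, 9, …) to
the prediction set — 43/21 for 64 samples. The sample order is fixed as
power density ascending, then time ascending, which makes the split
deterministic. Metrics: R is the Pearson correlation of predicted vs
measured; RMSEC/RMSECV/RMSEP are root mean squared errors of calibration,
cross-validation and prediction; RPD divides the (n−1) sample SD of the
prediction-set reference values by RMSEP (an exact prediction reports an
infinite RPD rather than failing). `compare_models()` declares the winner
by higher R<sub>p</sub>, breaking ties by lower RMSEP, and refuses to
compare models evaluated on different splits.

Replicate spectra are averaged per sample before modeling (the calibration
is over 64 chemistry values, not 192 spectra); `build_dataset()` can
instead repeat reference values per replicate for robustness studies.

## Determinism and problem sizes

All randomness flows from one user seed: the pipeline derives simulation,
PC-selection and network seeds from it by fixed offsets, and every
stochastic helper takes an explicit seed. Repeated runs with one seed are
`identical()`.

The test suite runs reduced searches (k up to 10–18, combinations of 2–3
intervals, ≤ 8 components) chosen so the whole suite completes in well
under a minute of search time while still exercising every code path,
including a 20-replicate planted-band recovery study.
`scripts/acceptance.R` runs the full-scale search (k = 15…30, sizes 2–4,
≤ 10 components, 5-fold CV) for both analytes.

## Known limitations

* PLS1 only (one response per model); no SIMPLS/kernel variants, no PLS2.
* No orthogonal signal correction, detrending or wavelet preprocessing;
  no vendor spectral formats (JCAMP-DX, SPC).
* The network has no regularization beyond early stopping; very noisy or
  tiny calibration sets can overfit, which the PC-count cross-validation
  mitigates but does not eliminate.
* The uniform wavelength grid means reported interval ranges are
  grid-derived; instruments with irregular pixel maps would need their own
  grid passed through `read_spectra()`.
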