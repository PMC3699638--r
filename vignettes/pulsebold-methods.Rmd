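---
title: "Physiological noise and cardiac pulsatility in white-matter BOLD: methods and design"
author: "pulsebold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiological noise and cardiac pulsatility in white-matter BOLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsebold)
```

## The problem

Resting-state BOLD fMRI time series fluctuate for reasons unrelated to
neural activity: respiration, pulsatile blood flow, vasomotion, slow
metabolic drift, and the scanner's own thermal noise. In white matter these
"noise" components are themselves of clinical interest — pulsatile energy
transmitted down a stiffening vascular tree should express itself as
increased signal fluctuation at the cardiac frequency, while chronically
hypoperfused lesional tissue (white matter hyperintensities, WMH, the
imaging signature of cerebral small vessel disease) should fluctuate less.
`pulsebold` implements two global, voxelwise metrics of these fluctuations
and the cohort statistics used to compare them across groups.

## The two metrics

**sigma_physio.** The total temporal variance of a voxel's time course is
decomposed under the square summation law

$$\sigma^2_{EPI} = \sigma^2_{physio} + \sigma^2_{therm},$$

where $\sigma^2_{therm}$ is estimated as the mean temporal variance over an
out-of-brain region of interest placed in an image corner (corner placement
avoids the EPI ghost, which propagates at half the field of view). The
physiological standard deviation $\sigma_{physio} =
\sqrt{\max(\sigma^2_{EPI} - \sigma^2_{therm},\,0)}$ is normalised to the
voxel's temporal mean and expressed in percent. Because variance is
sampling-rate invariant in expectation for a stationary process, this
metric is computable at any TR, including conventional 2 s acquisitions in
which the cardiac band is aliased.

**Cardiac pulsatility.** Each voxel's time course is Fourier transformed;
the one-sided amplitude spectrum is integrated over the bins whose centres
lie within 0.02 Hz of the cardiac frequency (identified from the
pulse-oximetry trace as the mean heart rate over the scan, divided by 60),
and divided by the nominal window width of 0.04 Hz. The resulting average
amplitude, normalised to the voxel mean, is the percent signal change at
the cardiac frequency. This metric requires cardiac-sampled data: with TR
0.25 s the sampling rate is 4 Hz and fluctuations up to the 2 Hz Nyquist
frequency — comfortably above resting heart rates near 1 Hz — are
unaliased. At TR 2 s the sampling frequency is 0.5 Hz and the package
refuses to compute the metric rather than integrate an aliased band.

Per-subject means of each metric are taken over eroded tissue masks — grey
matter (GM), normal-appearing white matter (NAWM = WM minus WMH), WMH and
optionally CSF — and one summary row per subject feeds the statistics
layer. The summary table is the sole contract between the two layers, so
summaries computed elsewhere can enter the statistics directly.

## Numerical conventions

Several discretisation choices are not dictated by the method's
description and are fixed here, documented because the absolute percent
values depend on them:

* **Spectrum scaling.** One-sided amplitudes are $|X_k|/n$ at DC (and the
  Nyquist bin for even $n$) and $2|X_k|/n$ elsewhere, so a pure sinusoid of
  amplitude $A$ centred on a bin reads $A$ at that bin. Parseval's identity
  under this convention, $a_0^2 + \sum a_k^2/2 + a_{Nyq}^2 =
  \overline{x^2}$, is asserted in the tests at $10^{-8}$ relative, and the
  fast transform is checked against a brute-force DFT at $10^{-10}$.
* **Window discretisation.** Bins are included when $|f - f_c| \le 0.02$ Hz
  (closed interval on bin centres); the integral $\sum a_k\,\Delta f$ is
  divided by the fixed width 0.04 Hz, with $\Delta f = 1/(n\,\mathrm{TR})$.
  A single-bin sinusoid of amplitude 2 % of the mean at $n = 500$, TR =
  0.25 s therefore reads $2 \times 0.008 / 0.04 = 0.4$ %.
* **Variance denominator** is $n - 1$ everywhere, so voxel and thermal-ROI
  variances are commensurable.
* **No detrending.** Variances are computed over the full retained time
  course; slow drift deliberately contributes to sigma_physio, and the
  phantom generator injects drift so the tests reflect that.
* **Negative decompositions.** Sampling error can push
  $\sigma^2_{EPI} - \sigma^2_{therm}$ below zero in quiet voxels; the value
  is clamped to zero and the voxel counted (`clippedCount`), preserving the
  nonnegativity of a standard deviation without hiding the event.
* **Erosion.** Tissue masks are eroded by smoothing the binary indicator
  with a 3 mm FWHM Gaussian (zero-padded at the grid edge) and keeping
  voxels whose smoothed value is at least 0.9 — a strict threshold that
  removes boundary voxels with any appreciable partial-volume mixing while
  preserving mask cores. Both the FWHM and the threshold are exposed in
  `runConfig()`.
* **Thermal ROI.** Default 8 x 8 in-plane blocks spanning all slices; the
  default policy picks the corner with the lowest mean signal (ghost
  avoidance), with fixed-corner and four-corner-union policies available.
  On homogeneous noise the one- and four-corner estimates agree to within
  a few percent, and the choice moves the sigma_physio metric by far less.

## The amplitude noise floor

An integrated amplitude spectrum is a magnitude statistic, so white noise
contributes a positive floor to the pulsatility metric: a pure-noise bin
has a Rayleigh-distributed amplitude with mean $\sigma\sqrt{\pi/n}$, and
the signal bin follows a Rice distribution. At a thermal SNR
(mean/SD) of 50 and $n = 500$ this floor raises a 0.4 % injection to an
expected reading of about 0.53 %. The package does not subtract this floor
— the metric is reported as defined — but `pulsatilityTruth()` computes the
analytic expectation (Rice mean at the signal bin, Rayleigh mean at the
rest) so that recovery tests compare the pipeline against the correct
expected value rather than the noiseless one. The floor is common to all
groups at equal thermal noise and cancels in group contrasts.

Two practical consequences are worth knowing. First, off-bin cardiac
frequencies leak amplitude across bins, and magnitudes do not add linearly,
so absolute pulsatility values are convention- and frequency-grid-
dependent; recovery assertions use on-bin heart rates (60 bpm at the
default grids). Second, heart-rate variability widens the cardiac peak —
precisely the reason the integration window is ±0.02 Hz rather than a
single bin.

## The phantom generator

`simulateCohort()` renders fully synthetic cohorts in which every
acceptance property is checkable against injected truth. Each voxel follows

$$S(t) = S_0\,[1 + c(t) + r(t) + b(t) + d(t)] + \varepsilon(t)$$

with a cardiac sinusoid $c$ (optional 2f/3f harmonics), a respiratory
sinusoid $r$ at 0.3 Hz, a broadband physiological process $b$ (white
Gaussian noise low-pass filtered at 0.15 Hz and rescaled per voxel to an
exact sample SD — the cutoff keeps it separable from both the cardiac
window and the respiratory line), a linear drift $d$, and white thermal
noise $\varepsilon$. Cardiac and respiratory phases, drift and heart rate
are shared across a subject's voxels; broadband and thermal noise are drawn
independently per voxel. The continuous-time model is rendered on a fine
grid (0.25 s) and subsampled, so a 2 s TR rendering aliases the same
physiology rather than re-drawing it — this is what makes the
decimation-invariance test of sigma_physio meaningful.

Geometry is a concentric-ring phantom (CSF core, WM annulus, GM ring) with
the corners left free for the thermal ROI, and a contiguous lesion grown
inside WM by breadth-first expansion for the disease group. Rings rather
than anatomy: the pipeline only needs class contiguity, background corners
and lesion-in-WM. Ring radii are jittered a few percent per subject so
anatomical covariates (WM volume) genuinely vary; the WM volume covariate
is recorded from the continuous ring geometry, as a high-resolution
anatomical segmentation would supply it, because voxel counts on the
reduced test grids are so coarsely quantised that they can degenerate to a
constant within a cohort.

Cardiac harmonics default to zero: at 4 Hz sampling the second and third
harmonics of a resting heart rate sit at or above the Nyquist frequency
and would alias — the third harmonic of 60 bpm lands exactly back on the
fundamental — which would corrupt recovery oracles. The parameters exist
for users who want that realism.

### Default study conditions

The default `cohortDesign()` emulates the study the pipeline is built for:
three cohorts — 11 young controls (YC, age 25.4 ± 3.2), 10 elderly controls
(EC, 65.8 ± 3.1), 7 small-vessel-disease subjects (SVD, 70 ± 8.6), with the
published sex ratios; a cardiac-sampled acquisition of 64 x 64 x 4 voxels
(3 x 3 x 5 mm) and 510 volumes at TR 0.25 s, of which the first 10 are
discarded; a conventional acquisition of 128 volumes at TR 2 s with none
discarded; heart rates drawn from N(60, 5) bpm and held constant within a
subject; lesions occupying 25 % of WM in SVD subjects.

Tissue signal amplitudes were solved once, analytically, so the injected
WM sigma_physio sits near the reported white-matter cohort means (about
0.6 / 1.0 / 1.15 % for YC / EC / SVD) with pulsatility graded YC < EC < SVD
and lesions below NAWM — the direction of effects the analysis is designed
to detect, encoded as generator truth. Between-subject variation has two
levels: a global physiology scale per subject (CV 0.20) shared by all
tissue amplitudes, and smaller tissue-specific jitter (CV 0.08). The shared
scale is what gives the paired NAWM-vs-WMH contrast its within-subject
correlation — paired t statistics land in a realistic range (~5) while the
pooled effect size stays near 1-2 — and leaves one-way F statistics for
the group effects in the 10-40 range rather than the hundreds a purely
independent draw would produce.

Per-volume head displacement means differ slightly by group (0.040 / 0.046
/ 0.058 mm) with wide between-subject spread, so cumulative motion over a
full 500-volume course averages in the low tens of millimetres and the
motion comparison between elderly groups is usually non-significant, as a
covariate of non-interest should be.

### What the phantom does not emulate

No EPI ghosting (beyond an optional corner artifact for testing ROI
placement), distortion, motion, inflow effects, spatially varying coil
sensitivity, heart-rate variability within a scan (optional), or 1/f
physiological spectra. Passing phantom tests therefore demonstrates that
the estimators and statistics are correct under the stated signal model,
not that the metrics are unbiased on real scanner data.

## The statistics battery

`runCohort()` reproduces the study's test sequence over the summary table:
one-way ANOVA of NAWM metric means across the three groups (df 2, 25 at
the published cohort sizes); pooled-variance post-hoc t-tests for the three
pairwise comparisons with Bonferroni correction at m = 3; ANCOVA by model
comparison (`value ~ covariates` vs `value ~ covariates + group`, a Type
III-style group test) with thermal noise as one covariate (df 2, 24) and
thermal + WM volume + WM partial-volume estimate as three (df 2, 22);
paired NAWM-vs-WMH t-tests within the lesion group with Cohen's d; an
unpaired motion comparison and motion-metric correlations; Levene's test
on absolute deviations from group means and Shapiro-Wilk normality per
group; and the per-subject GM-vs-NAWM voxelwise contrast tallied per group.

Choices where the convention was open: Cohen's d defaults to the classic
pooled-SD form even beside the paired test (both variants are reported in
the output note); post-hoc tests are Student t with pooled variance, with
Welch available by flag; Bonferroni is applied only to the three-test
cohort family; subjects with missing tissue values (controls have no WMH)
are dropped listwise per test; the intra-subject GM-vs-NAWM comparison is
an unpaired t-test across voxel values at alpha 0.05, the simplest reading
of a per-subject tissue contrast. Type-I error of the wrapped tests is
verified by Monte-Carlo calibration (about 5 % rejection at alpha 0.05
over 200 null replicates).

## Problem sizes used in tests

The test-suite and verification-script phantoms run a reduced profile —
20 x 20 x 2 voxels, 210 volumes (200 retained) at TR 0.25 s, with a 4 x 4
thermal corner — chosen as the smallest grid that preserves every
geometric property the pipeline touches: a multi-voxel rim survives
erosion, lesions remain contiguous and interior to WM, and the corner ROI
never touches tissue. Cohort-level claims are checked over 20 seeded
replicates of the graded design and 100 of a null design in which all
groups share the elderly-control parameters. The full-size default design
(64 x 64 x 4 x 510) runs the identical code path and is exercised by
`runDemo()` consumers who want it; only simulation volume changes.

## Known limitations

* Absolute pulsatility percentages are tied to the spectrum scaling and
  window discretisation documented above; comparisons across software with
  different FFT conventions require renormalisation.
* The cardiac frequency is taken from the pulse trace mean (or median);
  no spectral peak search is attempted, so a corrupted trace shifts the
  window rather than failing loudly (the plausibility band at read time
  is the guard).
* sigma_physio inherits drift and respiration by design; it is a
  broadband, not cardiac-specific, measure — the very property the
  pulsatility metric exists to sharpen.
* Masks must already be in BOLD space; no registration is performed or
  checked beyond grid-shape equality.
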