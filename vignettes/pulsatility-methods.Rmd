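---
title: "Measuring microvascular pulsatility with pulsemap: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring microvascular pulsatility with pulsemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsemap)
```

## The measurement problem

Cerebral blood flow is pulsatile: every heartbeat drives a pressure wave
through the vascular tree that modulates both flow velocity and vessel
caliber. In the microvasculature these modulations are small, fast (a mouse
heart beats at 8-11 Hz), and spatially heterogeneous, so quantifying them
needs full-field imaging at hundreds of frames per second and estimators
that average over many hundreds of heartbeats. `pulsemap` implements such an
estimation pipeline for two complementary modalities:

* **Laser speckle contrast imaging (LSCI)** gives wide-field relative
  perfusion maps at ~200 fps. Moving red blood cells blur the speckle
  pattern, reducing the local spatial contrast
  $K = \sigma(I)/\langle I\rangle$ (computed over a 5x5 pixel
  neighborhood); the blood flow index $BFI = 1/K^2$ is a standard relative
  perfusion measure.
* **Two-photon line scans (TPM)** repeatedly sweep a single line across one
  capillary, giving a space-time image of the lumen cross-section at
  millisecond resolution from which diameter and wall-position time series
  are extracted.

The target quantities are pulsatility indexes over the cardiac cycle,
$PI = (x_{max} - x_{min}) / \langle x \rangle$, evaluated for flow
($PI_{BFI}$) and diameter ($PI_D$) per vessel or region, and - for
capillaries - a cardiac-band spectral signal-to-noise ratio
$SNR = P_c / P_n$ where $P_c$ is the topographic prominence of the most
prominent spectral peak in the cardiac band (9-13 Hz) and $P_n$ the noise
pedestal, defined as peak height minus prominence. $SNR > 1$ thus means the
peak carries at least twice the power of the local noise floor.

## The representative cardiac cycle

Individual heartbeats in the whole-field contrast time course have
amplitudes comparable to the speckle estimation noise, so all LSCI
pulsatility quantities are computed on an ensemble-averaged *representative
cycle*:

1. The field is masked to the usable area and each frame reduced to its
   mask-averaged contrast, giving one time course (116,400 points for a
   600-s recording at 194 fps).
2. The dominant cardiac frequency $f_0$ is the argmax of the discrete
   spectrum in a physiological band (default 5-15 Hz).
3. Cycle boundaries are local minima of the time course, found with a
   sliding window of half a nominal period, merged if closer than the
   shortest admissible period, and paired into cycles whose duration lies
   within $(1 \pm 0.3)\,f_s/f_0$.
4. Each cycle is scored by mean, SD, magnitude, duration, start-to-end
   difference, and noise-spike count (counter-directional steps larger than
   20% of the cycle magnitude on a monotone limb).
5. Cycles deviating from the feature median by more than 2 SD on any
   screened feature, or with more than 2 spikes, are rejected. Screening is
   single-pass.
6. Accepted cycles are linearly resampled on their own time base to
   $n_{phase} = \mathrm{round}(\mathrm{median\ duration} \times
   \mathrm{interpolation\ factor})$ samples and averaged pointwise, per
   pixel. Because durations differ by a few percent, the pooled samples
   form an irregular grid denser than the frame clock ("temporal
   super-resolution").
7. The averaged contrast cycle is converted to $BFI = 1/K_{cycle}^2$, from
   which PI maps and per-structure summaries are computed.

Averaging contrast first and converting to BFI afterwards (rather than the
reverse) follows the step order above; since the conversion is monotone and
smooth, and per-phase contrast noise after averaging hundreds of cycles is
well below 1%, the difference between the two orders is negligible.

### Numerical choices

* **Population (1/N) standard deviation** in the contrast window - the
  convention in the speckle literature. At N = 25 this carries a known
  finite-sample factor ($E[\hat K] \approx 0.975\,K$ for Gaussian noise);
  since the factor is multiplicative and common to all pixels, and PI is
  scale-invariant, it cancels from every pulsatility quantity. The test
  suite asserts the estimator mean against this finite-sample expectation.
* **Edge policy**: contrast is computed only where the full window fits;
  the border band is flagged undefined (`NA`) rather than estimated from a
  truncated window, which would bias the statistics. Undefined values are
  carried as `NA` throughout and excluded from means.
* **Minima localization on a lightly smoothed trace**: candidate minima are
  located on a moving-average copy (quarter-period window) of the time
  course, then refined to sub-sample positions by a parabolic fit. The raw
  trace is used for everything else. Rationale: the diastolic foot of the
  waveform is flat relative to speckle noise, so raw argmin positions
  jitter by several frames, smearing the ensemble peak; smoothing shifts
  all boundaries by the same small amount (a pure phase offset that no PI
  quantity depends on) while stabilizing them. Sub-sample boundaries avoid
  quantizing phase alignment to the frame clock.
* **Cardiac-peak significance gate**: before any cycle gating,
  `cardiac_peak_ratio()` compares the peak to the median spectral power in
  the cardiac band. Recordings with a heartbeat score ratios in the
  thousands; pure noise stays in single digits (the max/median of ~600
  exponential bins is about $\ln 600 / \ln 2 \approx 9$). Below the default
  threshold of 50 the pipeline reports zero pulsatility instead of gating
  on noise minima - gating noise produces a spurious PI of order 0.1 from
  a handful of surviving pseudo-cycles, which is a measurement artifact,
  not a measurement.
* **Rejection rule degeneracies**: if a feature's SD is zero (identical
  cycles) nothing is rejected on it; if every cycle would be rejected the
  set is flagged with an error status rather than silently emptied.

## Dynamic vessel segmentation

Vessel ROIs (user-drawn polygons labeled artery or vein) are reduced to a
per-phase diameter and intra-vessel BFI:

* The **centerline** is estimated once, on the phase-mean BFI image:
  Gaussian smoothing (sigma = 2 px), intensity weights above the median,
  principal axis from the weighted second-moment tensor, per-bin weighted
  centroids across the axis, and a smoothing spline. An anisotropy score
  (eigenvalue ratio) below 2 raises a "no vessel found" error - a uniform
  patch has no centerline. The centerline is *not* re-estimated per phase;
  sub-pixel wall motion is captured by the profile classification, and a
  fixed centerline avoids phase-to-phase geometric jitter.
* The **average cross-profile** samples the image along the perpendicular
  of every centerline point at 0.25-px spacing (bilinear interpolation) and
  averages along the segment. Because centerline points are not
  pixel-aligned, the pooled samples oversample the cross-section - the
  spatial analogue of the temporal super-resolution above.
* **Classification** uses exhaustive minimum within-class variance
  thresholding over the observed profile values (ties broken toward the
  lower threshold); the base diameter is the longest contiguous
  supra-threshold run (robust to side-branch bleed-in) times the step,
  with run edges refined by linear interpolation to the midpoint of the
  two class means. The midpoint (half-maximum) convention is used for the
  crossing level because the raw threshold sits asymmetrically in the
  intensity gap when the two classes have unequal sizes, which would bias
  the width by up to a pixel.
* **Edge-model width.** For vessels whose width is within a few times the
  effective point-spread function (the 5x5 contrast window plus profile
  interpolation), the two edge spreads overlap and any threshold-crossing
  width under-responds to true width changes by tens of percent - the
  profile peak itself moves with width, dragging the adaptive level along.
  `trace_vessel()` therefore refines each phase's diameter by
  least-squares fitting a double-logistic lumen model
  (`fit_profile_width()`), initialized from the classified run, and reads
  the width parameter; the crossing-based estimate is the fallback when
  the fit fails or disagrees grossly. The fit runs in contrast (K) space,
  where the physical wall transition is logistic-like; the convex
  `1/K^2` map would skew it. On oscillating-width phantoms this restores
  amplitude fidelity of `PI_D` from roughly -30% (crossing-based) to a
  few percent.
* **Intra-vessel BFI from the lumen core** (central half of the fitted
  width): samples near the wall are partial-volume mixtures with the
  background and dilute the flow modulation.
* **Parenchyma ROIs** (nominally 5000 px, +-10% tolerated with a warning)
  skip segmentation; their per-phase BFI is the pixel mean over the ROI.

Accuracy degrades for vessels only a few pixels wide: the profile of a
6-px vessel is already dominated by its edges. The suite requires <= 1 px
diameter error for widths >= 6 px and <= 5% spread across orientations
{0, 30, 60, 90} degrees.

## Capillary line-scan analysis

Each line scan is segmented per time column into lumen and background by
two-class 1-D k-means, deterministically initialized from whole-scan
half-maximum statistics (zero-variance columns are excluded as artifacts).
Wall coordinates are refined to sub-pixel positions by interpolating to the
inter-class midpoint intensity. Columns are excluded when no usable run
exists, the run touches the scan edge (which also catches saturated
frames), or the diameter jumps by more than 50% of the local half-second
median. The result is a *gapped* series - exactly the setting for the
Lomb-Scargle periodogram, which is computed per non-overlapping 5-s window
(windows retaining under 20% of their nominal samples are skipped) on a
fixed 1-30 Hz grid with 0.1 Hz spacing, in the standard unnormalized
(Press) convention that reduces to the classical periodogram for regular
sampling, and averaged over windows and over the 3-4 cross-sections of the
same capillary. Averaging w windows shrinks the noise-floor variance
roughly as 1/w.

Diameter spectra (wall separation) quantify true caliber pulsatility;
wall-*midpoint* spectra quantify rigid displacement of the vessel by the
surrounding tissue. The midpoint is the right displacement observable: a
pure width oscillation moves both walls individually (each by half the
amplitude), so single-wall spectra mix the two effects, while the
common-mode midpoint cancels caliber changes exactly. A translating lumen
of fixed width produces a high midpoint SNR and a null diameter SNR, and
vice versa - the test suite checks this separation on phantoms, and `orientation_summary()` bins per-capillary SNR into
20-degree orientation bins (with a mean-normalized variant) to expose the
orientation dependence that distinguishes tissue displacement from
pressure-wave-driven caliber changes.

## The synthetic-data generators

Every estimator above is validated against phantoms with known ground
truth, generated by `make_cardiac_trace()`, `render_speckle_video()`, and
`render_linescan()`.

**Cardiac drive.** Beats are concatenated with period jitter (default 3%
SD, truncated at 3 sigma) around a 10 Hz rate, the center of the murine
range. The pulse is a beta-shaped wave $\varphi^2 (1-\varphi)^6$ (fast
systolic upstroke, peak at 25% of the cycle, slow diastolic decay) plus a
small parabolic mid-cycle component (weight 0.2) that acts like a dicrotic
hump and keeps the diastolic foot at a finite slope. A perfectly flat foot
would make cycle onsets ill-localized in a way real waveforms are not.
Modulation depths are parameterized directly by the target PI of the
noiseless waveform, which the generator also returns.

**Speckle videos.** The intensity model is
$I(x, y, t) = I_0 (1 + K_{target}(x, y, t) \, Z)$ with $Z$ white
unit-variance noise, quantized to 16-bit camera counts, so the 5x5 spatial
contrast estimator recovers $K_{target}$ in expectation. This is
deliberately an *estimator-faithful* noise model, not a coherent speckle
simulation: it reproduces the local contrast statistics the pipeline
consumes and nothing else about speckle optics (no spatial speckle
correlation, no exposure-time physics). It must not be used for optical
design questions. Geometry is a straight vessel (default 12 px wide,
baseline contrast 0.2) through a parenchymal background (contrast 0.35);
vessel interior BFI, vessel width, and - by default - background BFI follow
the cardiac drive. The pulsing background reflects the perfused capillary
bed, which is what gives the real whole-field time course its cardiac
modulation in the first place; without it, whole-field cycle detection
would be physically unrepresentative. Corrupted beats (for QC tests) scale
the waveform amplitude by 2.5 on randomly chosen beats.

**Line scans.** A smoothed top-hat lumen (logistic edges, 0.7 px) on a dark
background with Poisson (shot-like) noise; width and center can oscillate
sinusoidally to emulate diameter pulsatility and rigid displacement, and a
configurable fraction of columns is railed to a saturation value to
emulate artifacts.

All generators are deterministic given their seed, and every sidecar truth
value is recomputable from the spec alone.

### What passing phantom tests does and does not show

The phantoms validate the estimation chain - contrast statistics, cycle
gating, ensemble averaging, segmentation geometry, spectral estimation -
under the statistical structure the estimators assume. They do not contain
breathing or motion artifacts beyond the modeled ones, vessel curvature,
branching, flow-dependent speckle decorrelation physics, focal drift, or
fluorophore bleaching; agreement on phantoms therefore bounds estimator
error, not biological measurement error.

## Validation conditions and problem sizes

The test suite exercises desk-scale versions of the study conditions: 60-s
recordings of a 128x128 px field at 194 fps (about 600 heartbeats at
10 Hz, 3% jitter) for end-to-end recovery, with prescribed flow
pulsatility $PI_{BFI}^* \in \{0.05, 0.15, 0.30\}$ recovered within 10%
relative error, diameter oscillation (10 to 11 px) recovered within 20%,
and null phantoms reporting PI below 0.02; 30-s line scans at 1 ms line
period for the spectral suite. Smaller fields and durations appear
throughout the unit tests where the property under test does not need the
full ensemble.

Two residual biases are worth knowing about. First, the PI of a
noise-contaminated cycle is biased upward because max and min are extreme
statistics; with ~400-600 averaged cycles this contributes a few percent
at $PI^* = 0.05$ and is negligible at 0.15 and above. Second, boundary
smoothing shifts the representative cycle by a constant phase offset
(harmless to every reported quantity). Longer recordings shrink the first
bias as $1/\sqrt{n_{cycles}}$; the 600-s recordings the method is designed
for make it negligible at all realistic PI values.

## Known limitations

* BFI is a relative index; no absolute perfusion calibration is attempted,
  and values are comparable only within one optical configuration.
* The vessel tracer assumes one dominant, roughly straight, bright vessel
  segment per ROI; forks and strongly curved segments need narrower ROIs.
* Diameter estimates for vessels narrower than ~6 px carry errors of order
  1 px; vessels at that scale are better measured with TPM line scans.
* The cardiac band (9-13 Hz for TPM SNR, 5-15 Hz for LSCI detection) is a
  parameter, not adaptive per animal.
* Multi-exposure or temporal-contrast speckle variants are out of scope.

## A worked example

```{r example, eval = FALSE}
# a 20-s, 64x64 phantom with 15% flow pulsatility
ph <- speckle_phantom_spec(size = c(64L, 64L), duration_s = 20, seed = 7)
wf <- cardiac_waveform_spec(rate_hz = 10, jitter = 0.03, pi_bfi = 0.15)
sim <- render_speckle_video(ph, wf)

b <- run_pipeline(run_config(
  sim$stack, rois = list(roi_rect("a1", "artery", 10, 10, 44, 44))))
b$qc$heart_rate_hz      # ~10 Hz
b$structures            # per-structure <BFI>, <D>, PI_BFI, PI_D
```

The same stages are available individually (`spatial_contrast()`,
`field_mean_timecourse()`, `detect_cycles()`, `representative_cycle()`,
`pi_map()`, `trace_vessel()`, ...) and through the `exec/pulsemap` command
line.
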