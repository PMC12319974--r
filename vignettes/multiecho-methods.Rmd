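---
title: "Models and design choices in mebold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in mebold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mebold)
```

This vignette documents the models the package implements, the tunable
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical decisions taken where the design was open.

## 1. Signal model

The multi-echo gradient-echo magnitude signal is modeled as
monoexponential in echo time:

$$S_e(v, t) = S_0(v)\,\exp\!\big(-\mathrm{TE}_e / T_2^*(v) - \mathrm{TE}_e\,\Delta R_2^*(v,t)/1000\big),$$

with TE and $T_2^*$ in ms and the BOLD fluctuation entering as a
relaxation-rate modulation $\Delta R_2^*$ in 1/s. This makes the
echo-time dependence of functional contrast *emergent* rather than
assumed: the fractional signal change is approximately
$\mathrm{TE} \cdot \Delta R_2^*$, so later echoes carry proportionally
more BOLD contrast, which is exactly why T2\*-weighted echo combination
works. The derived relaxation rate is $R_2^* = 1000 / T_2^*$ (1/s).

Complex thermal noise is added per channel: the noiseless signal is
rotated by a small static phase map, independent Gaussian noise of SD
$\sigma$ is added to the real and imaginary parts, and magnitude and
phase are taken. Where there is no signal (outside the brain mask, and in
the trailing noise frames acquired without excitation) the magnitude is
therefore Rayleigh-distributed with scale $\sigma$ — a property the test
suite checks with a Kolmogorov–Smirnov test.

## 2. The synthetic generator: what it emulates

* **Age-specific tissue.** $T_2^*$ maps are drawn from truncated normals
  with the adult (48.89 ± 12.23 ms), child (59.34 ± 13.96 ms) and infant
  (93.84 ± 27.04 ms) cortical distributions, lightly smoothed (1-voxel-SD
  kernel) for spatial autocorrelation and restandardized so the sampled
  moments match the preset before clipping. Bounds cover ±3.5 SD, so
  clipping is negligible; they exist to exclude non-physical values.
* **Network structure.** A spherical brain mask is tiled into contiguous
  parcels; parcels belong to K networks whose latent series are an AR(1)
  process (timescale 8 s, approximating the temporal autocorrelation of
  BOLD) with a chosen stationary covariance. Each voxel mixes its
  network's series with an idiosyncratic AR(1) component
  (`idioFraction`, default 0.3), so parcel averages are cleaner than
  single voxels — the property that makes parcellation increase
  reliability in real data too.
* **Physiological noise and drift** are sinusoidal (respiration, default
  15 breaths/min) and linear terms proportional to the local baseline
  signal.
* **Motion** is simulated as parameter traces: a slow random walk plus
  step-like spikes of configurable magnitude and probability, with an
  optional global signal perturbation on spike frames. Rigid-body
  resampling of the volumes is deliberately **not** simulated; the
  quality-control logic the package exercises (FD computation, band-stop
  filtering, censoring, run-level rules) operates on the traces.
* **Thermal level.** The default per-channel SD of 1 at $S_0 = 100$ was
  chosen so that raw single-run temporal SNR lands in the 40–70 range
  typical of adult 3 T precision fMRI at 2 mm resolution, and frozen. At
  far noisier settings the patchwise BOLD singular values sink below the
  noise edge and *any* hard-thresholding denoiser would remove the neural
  signal along with the noise — a regime outside the one being modeled.

Not emulated: surface geometry and grayordinates (the package is
volumetric), k-space/reconstruction effects, slice timing, susceptibility
distortion, or true rigid-body motion of the volumes. Passing tests
therefore demonstrate the statistical machinery on data with known truth,
not performance on real acquisitions.

## 3. Thermal denoising

Each echo is denoised independently as complex data
(magnitude·e^{i·phase}). Cubic patches (default: the smallest cube with
volume ≥ 11 × the frame count, the conventional spatial:temporal ratio;
stride = half the edge, with a final patch flush against each boundary)
are unfolded into Casorati matrices and SVD hard-thresholded: singular
values at or below the pure-noise level τ are zeroed, survivors kept
unchanged. Overlapping patch reconstructions are averaged with uniform
weights by coverage count. Noise frames are excluded from the patch time
dimension and passed through unchanged, and are never counted in tSNR.

The threshold is the Monte-Carlo mean largest singular value of an m×n
complex Gaussian matrix with per-channel SD σ (seeded; default 10
draws). The convention matters: σ is *per channel*, so matrix entries
have total SD σ√2 and the asymptotic Marchenko–Pastur edge is
σ√2(√m + √n), which the MC estimate must match within 5% for m, n ≥ 50
(tested). σ comes from the SD of the real and imaginary parts over the
noise-frame voxels; without noise frames a theoretical fallback uses
1/√2 × a robust spread of the most signal-free region, flagged as such.
Without phase data the same procedure runs on magnitude alone, with a
warning, since the residual noise is then non-Gaussian.

Spatially varying noise (g-factor) is assumed uniform, matching the
generator; a g-factor map is accepted for pre-normalization but never
estimated.

**Spatial-precision guard.** The package asserts that denoising adds
less than half a voxel of FWHM *beyond the noiseless signal's own
smoothness*. The naive alternative — comparing denoised to raw — is
uninformative on synthetic data: spatially white thermal noise drags the
raw ACF estimate toward the voxel size, so even perfect denoising
"increases" apparent smoothness up to the signal's intrinsic value.

## 4. T2\* mapping and combination

The fit is ordinary least squares of log mean signal against TE. When
the thermal noise level is known (noise frames present), the per-echo
temporal mean is first noise-floor corrected via the second moment:
under complex Gaussian noise $E[M^2] = S^2 + 2\sigma^2$, so
$\hat S = \sqrt{\max(\overline{M^2} - 2\sigma^2, 0)}$. Without the
correction the Rician floor flattens the decay at low-signal late echoes
and biases $T_2^*$ upward by ~25% at SNR 10; with it the median bias is
below 0.3% (tested at SNR 10, 200 frames). The correction is applied to
raw data only — denoised data has had its noise removed, and correcting
it with the raw σ would over-subtract.

Echoes whose (corrected) mean is non-positive are dropped from the tail;
voxels with fewer than two usable echoes are flagged invalid rather than
erroring. $T_2^*$ is clipped to [2, 500] ms — wide enough for the infant
95th percentile with headroom, tight enough to suppress log-fit blowups;
zero-decay voxels land on the upper bound. Combination weights
$w_e \propto \mathrm{TE}_e e^{-\mathrm{TE}_e/T_2^*}$ are computed from
the run-average $T_2^*$ map (not per frame); invalid voxels fall back to
equal weights and are counted.

## 5. Motion QC and nuisance regression

FD is the sum of absolute backward differences of the translations plus
50 mm (the standard head-radius convention) times those of the
rotations; the first frame is defined FD = 0 and retained. All stated
boundaries are strict, exactly as printed: censoring removes FD > 0.2 mm
(connectivity) or > 0.3 mm (interpolation), tSNR averaging keeps runs
with > 90% retained at 0.3 mm, and the infant rule drops runs with
< 30% retained.

Respiratory band-stop filtering of the motion parameters uses a
zero-phase second-order Butterworth notch (band in breaths/min, ÷60 to
Hz). When the band's lower edge reaches Nyquist — as for neonatal
respiration (30–60 bpm) at TR ≳ 1 s — the filter is skipped explicitly
with a recorded reason, never silently.

Cleaning follows the order interpolate → filter → regress → re-censor:
frames censored at 0.3 mm are linearly interpolated from the nearest
retained neighbors (edges held constant) so their spikes cannot leak
through the 0.009–0.08 Hz zero-phase Butterworth band-pass; the filter is
applied identically to data and to the 36 confound columns (6 motion + 3
tissue means, their backward-difference derivatives, and all squares);
voxelwise OLS residuals are returned with means restored; and the
interpolated frames are re-excluded before any correlation. The "global"
tissue mean is the mean over the whole analysis mask; the mask is
configuration, not a hard-coded choice. Linear (not spectral)
interpolation was chosen for transparency. Despiking is out of scope.

## 6. Reliability

Runs are permuted (seeded), split into halves by run (odd counts put the
extra run in the held-out half), and the held-out half's connectivity
matrix — over all its retained frames — is compared against matrices
built from growing consecutive amounts of retained data
(⌊minutes·60/TR⌋ frames) from the other half. Reliability at each grid
point is the mean over nodes of the Pearson correlation between matching
matrix rows, diagonal excluded; mean and SD are reported across
permutations (default 100; the pipeline's desk-scale default is 25). A
Fisher-z variant of the row correlation is available and preserves
condition ordering (tested); raw r is the default.

Two structural facts the implementation surfaces deliberately: absolute
reliability also depends on the held-out half's size (tested as a
monotone trend), and parcel curves dominate dense curves because parcel
averaging cancels node-specific noise. The latter is also why the
pipeline's condition comparison uses **dense** nodes (a regular in-mask
voxel subsample, default 600): parcel averaging already removes
voxelwise thermal noise, so parcel reliability barely responds to
thermal denoising, while dense reliability — the headline quantity in
precision-mapping work — shows the full benefit.

## 7. Problem sizes and determinism

Every stochastic step takes an explicit seed and is bit-reproducible;
the pipeline writes a JSON provenance record of every parameter. The
test suite exercises the full chain at desk scale: tissue-map moments at
64³; the four-condition grid at 24³ with 4 × 150-frame runs and 25
permutations; large-sample connectivity identities at 10–20k frames on
single-echo 10³ grids; everything else smaller. These sizes were chosen
so the complete suite runs in a few minutes while leaving each check
several standard errors of headroom.

## 8. Known limitations

* Volumetric stand-ins for surface quantities: cortical "vertices" are
  in-mask voxels; parcels are geometric tilings, not anatomical atlases.
* The magnitude-only denoising fallback thresholds real-valued matrices
  with the complex-noise edge, which is slightly conservative; it is a
  flagged fallback, not the recommended path.
* The FWHM estimator uses a Gaussian ACF model only (kernel-equivalent
  width combined in quadrature with the voxel size); it is meant for
  comparisons between conditions, not for parity with any external
  smoothness estimator.
* MEICA-style component classification is intentionally absent.
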