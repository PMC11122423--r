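---
title: "Reconstruction of spectroscopic SMLM data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction of spectroscopic SMLM data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dssmlm)
```

## The imaging model

Spectroscopic single-molecule localization microscopy (sSMLM) inserts a
dispersive element (grating or prism) into the emission path of a
localization microscope. Each camera frame then contains two images of the
same stochastically blinking emitters: a zeroth-order *spatial* image and a
first-order *spectral* image in which every emitter is drawn out along the
dispersion axis according to its emission spectrum. Matching a localization
$(x_i, y_i)$ in the spatial image with its dispersed trace yields a spectral
signature $\lambda_i$ (here: the spectral peak) per blinking event, giving a
record $(F_i, x_i, y_i, \lambda_i)$ per event. The price is photon
starvation: the grating splits roughly 1:3 between the two orders, so both
images are dim; the package's purpose is a reconstruction chain that
tolerates this.

The simulator (`simulate_stack()`) implements exactly this forward model:

* emitters per frame are Poisson with mean `density × FOV area`; the
  default density 0.1 molecules/μm² keeps point-spread functions (PSFs)
  non-overlapping;
* the spatial PSF is a pixel-integrated 2-D Gaussian (`psf_sigma`, default
  1.3 camera px) carrying `1 − split_ratio` (default 0.25) of the photons;
* the spectral trace is the dye's emission spectrum resampled onto the
  pixel grid through the linear dispersion (`nm/px`), convolved along x
  with the PSF profile and spread in y by the PSF profile, carrying
  `split_ratio` (0.75) of the photons;
* shot noise is Poisson on expected counts (signal + uniform background)
  and Gaussian read noise is added.

Ground truth (continuous positions, photon counts, dye identities) is
returned with the frames, which is what makes supervised training and all
quantitative evaluation possible.

### Calibrated noise defaults

Per-event photon counts are lognormal. The literature values for the
original instrument's noise are not printed anywhere, only that simulation
parameters were chosen to match the experimental data. The one quantitative
anchor available is the structural similarity (SSIM) between raw noisy
spectral-PSF crops and their noise-free counterparts, reported at ≈0.59 for
dye-labeled data. We therefore calibrated the labeled-mode defaults once —
`photon_mean = 2300`, `photon_sd = 690`, `background_rate = 1` photon/px,
`read_noise_sd = 1.5` e⁻ — so that the simulator reproduces that SSIM
(`scripts/acceptance.R` recomputes it at every run), and froze them. A
mean of 2300 photons per blink is typical for AF647 under dSTORM buffers.
The label-free mode keeps a 300-photon mean: intrinsic DNA photoswitching
emits an order of magnitude fewer photons than organic dyes. With the
spec-sheet-style placeholder values (1000 photons, background 10), the raw
ROI SSIM would be ≈0.13; even noiseless backgrounds cap it at ≈0.39 at 1000
photons, so the brighter calibrated world is forced by the stated
characteristic, not a preference.

### What the generator does not emulate

Single-molecule spectral heterogeneity (per-event spectral jitter), sCMOS
pixel-dependent noise maps, 3-D/astigmatic PSFs, dipole orientation
effects, fluorophore photobleaching kinetics, and sample autofluorescence
structure. Dye emission spectra are smooth two-sided Gaussians anchored at
published emission maxima (671 nm AF647, 699 nm CF680, 560 nm ATTO 542,
681 nm ATTO 655), i.e. synthetic stand-ins, not measured reference curves.
A green test therefore establishes correctness of the algorithms under this
idealized world, not instrument-level performance.

## The two networks

No deep-learning framework exists in the deployment environment, so both
networks are implemented from first principles in `src/nn_core.cpp`:
im2col convolutions batched into single BLAS GEMMs, manual
backpropagation (verified against finite differences), Adam in R, single
precision. This keeps the package dependency-free and CPU-trainable at the
scales used here.

### Emitter localization (U-Net)

`train_localizer()` fits a U-Net that maps a spatial image — bilinearly
resampled onto a grid upsampled by `upsampling` (default 4) — to a
same-size prediction grid with a unit-mass spike per emitter at
`round(position_px × upsampling)`. Encoder levels use two 3×3 convolutions
(ELU) and 2×2 max pooling; the decoder mirrors them with 2×2 transposed
convolutions and concatenating skips; a 1×1 linear layer emits the
prediction. The loss is

$$\ell_{loc} = \lVert (\hat y - y) \circledast g \rVert_2^2
  + \lambda \lVert \hat y \rVert_1$$

with $g$ a Gaussian kernel (sd `loss_kernel_sigma` = 1 fine px) and
$\lambda$ = 1. Several numerical choices matter:

* **$g$ is normalized to unit peak, not unit mass.** With unit-mass $g$
  and unit spikes, the squared-error reward for emitting a spike is
  $\sum g^2 \approx 0.08$, below its L1 cost of 1 — the all-zero
  prediction would be the global minimizer and training collapses to it.
  Unit-peak $g$ raises the reward to $\approx \pi\sigma^2 > 1$. The loss
  identities used in the tests (perfect prediction ⇒ loss = L1 mass;
  zero prediction against one spike ⇒ loss = $\sum g^2$) hold either way.
* **Per-spike target mass defaults to 100** (`spike_mass` in
  `localizer_spec()`). Even with the unit-peak kernel, unit-mass spikes
  leave the zero prediction as a basin that gradient training cannot
  escape: growing a localized spike from zero must cross an L1 barrier
  against a weak quadratic reward (a 150-epoch overfitting run on 64
  patches stayed exactly at the collapse loss). Amplitude-100 spikes —
  the convention of the reference implementation of this loss — make the
  squared-error term dominate while the L1 term keeps its sparsifying
  role.
* **The 1×1 output head is initialized at 0.01× He scale.** There are no
  normalization layers to tame a He-scaled head, whose random initial
  output otherwise dominates the early loss (~10⁵) and wastes the short
  training budget shrinking junk.
* **Normalization is background-median subtraction with one global scale**
  estimated from the training set and stored in the model. Per-image
  standardization would make the effective emitter amplitude depend on the
  emitter density of the image, breaking transfer from dense training
  patches to sparse test frames.

Inference (`predict_localizations()`) extracts 8-connected local maxima of
the clamped prediction grid above `threshold × max` and an absolute floor
`min_value` (in spike-mass units; keeps background-only frames silent),
merging maxima closer than `min_separation` (default: one camera pixel).
Grid indices convert to nm via `camera_pixel_size / upsampling`; no
sub-grid interpolation is applied, so the upsampling factor bounds the
quantization error (≈ `pixel/(U√12)` per axis).

### Spectral-PSF enhancement (residual DCNN)

`train_enhancer()` fits a 7-layer, 64-filter (3×3, ReLU) convolutional
network with an additive input–output skip — residual learning of the
noise — minimizing plain MSE between restored and noise-free spectral
ROIs. ROIs are 5×50 px (labeled) or 9×95 px (label-free), cropped by
`crop_spectral_roi()` vertically centered on the localization row and
starting horizontally at the pixel onto which the mode's window start
(620/500 nm) maps through the calibration. Each ROI is normalized by the
maximum of its noisy crop on the way in and rescaled on the way out;
negative outputs clamp to zero. The additive (rather than concatenative)
skip follows the denoising-CNN lineage the architecture comes from.

## Calibration, spectral analysis, post-processing

* **Calibration** (`fit_calibration()`): ordinary least squares of known
  laser-line wavelengths (405/488/532/552/637 nm) against measured peak
  pixel displacements; sub-pixel line positions come from 1-D Gaussian
  fits of the column-sum profile. The map is λ = slope × (spectral_x −
  spatial_x − reference_offset) + intercept, i.e. displacement-based with
  the zeroth-order position as reference, which is the form the
  downstream spectrum extraction needs. The offset is stored explicitly.
* **Spectra** (`extract_spectrum()`): plain column mean over all ROI rows,
  normalized to max 1 (the possibility of weighting rows is deliberately
  not taken — nothing in the source material suggests it); peak = grid
  argmax with ties broken toward lower wavelength; optional 3-point
  parabolic refinement behind a flag.
* **Filtering/channels**: inclusive windows (e.g. 640–700 nm AF647,
  670–730 nm CF680; two-color 550–610 / 650–710 nm); channel windows must
  be pairwise disjoint, everything else lands in `unassigned`.
* **Drift** (`correct_drift()`): localizations are split into `n_bins`
  frame blocks, each rendered as a lightly blurred 2-D histogram,
  FFT-cross-correlated against block 1, refined by a 3-point parabola per
  axis, and interpolated linearly per frame. Block 1 defines zero.
* **Spectral regression** (`spectral_regression()`): the reference
  algorithm's grouping thresholds are published elsewhere and not
  restated in our sources, so the implementation here is this package's
  own definition (a faithful stand-in): greedy frame-ordered chaining into
  open groups within 50 nm spatially, 10 nm spectrally and ≤5 frames gap,
  with photon-weighted centroids/wavelengths and summed photons. Weighted
  means match the photon-accumulation logic of the original. Precision
  of merged records improves as ~1/√N (tested by Monte Carlo).
* **Rendering**: 2-D histogram at the requested pixel size, optional
  Gaussian blur, count- or photon-weighted.

## Evaluation suite

Jaccard index TP/(TP+FP+FN) and lateral RMSE over matched pairs, with
one-to-one optimal (Hungarian) matching within a 100 nm radius — the SMLM
challenge convention; a greedy matcher is available for comparison. SSIM
follows the standard Gaussian-window form (sd 1.5, k₁ = 0.01, k₂ = 0.03,
data range from the reference image, replicate-edge filtering); it matches
scikit-image to 1e-6 on images large enough for the 11×11 window, and on
smaller images (5×50 ROIs) averages over the full map instead of cropping
the filter-support border. FWHM = 2√(2 ln 2)σ from a least-squares
Gaussian+offset fit. FRC splits the localizations randomly in half,
renders both halves, correlates ring-wise in Fourier space, smooths with a
3-ring moving average and reads the resolution at the fixed 1/7 threshold;
if the curve never crosses, the Nyquist length 2×pixel is reported as a
bound.

## Scaled-down training and what the tests establish

The reference training scale (15K patches of 208×208 px / 200 epochs for
the localizer; 143K ROI pairs / 30 epochs for the enhancer) needs hours of
GPU or CPU time. The test suite must run on one CPU in minutes, so
`tests/testthat/test-acceptance.R` trains both networks at reduced scale —
12K patches of 16×16 px (≥1 emitter each; at that patch area the
208-px-patch rule "≥3 emitters" would select only unrepresentative dense
clusters) for a depth-2, 8-filter U-Net, and a few thousand 5×50 ROI pairs
for a 5-layer, 8-filter enhancer — and evaluates on 100 held-out 64×64
frames exactly as the full-scale protocol prescribes. The localization
bounds asserted (JI, RMSE at 100 nm radius) are the full-scale ones; the
enhancer criterion at reduced scale is the prescribed fallback form
(restored SSIM strictly above noisy SSIM). Determinism: all training,
simulation and FRC splitting is seeded; identical seeds reproduce runs
bit-for-bit (single-threaded BLAS assumed).

## Known limitations

High-density (overlapping-PSF) frames are out of scope, as are 3-D
localization, uncertainty estimates, fiducial-based drift correction, and
ML-based spectral classification. The TIFF codec is deliberately minimal
(uncompressed grayscale baseline TIFF, 8/16-bit unsigned or 32-bit float)
because the deployment environment ships no R TIFF package. The spectral
regression stand-in reproduces the *mechanism* (photon accumulation across
re-identified blinks) but not necessarily the reference implementation's
exact grouping decisions.
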