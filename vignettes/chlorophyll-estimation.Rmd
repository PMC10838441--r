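---
title: "Estimating leaf chlorophyll from Vis-NIR hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf chlorophyll from Vis-NIR hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Total chlorophyll is a standard physiological indicator for leafy crops:
it tracks nitrogen status, light acclimation and general plant health.
The reference measurement is a handheld transmittance meter (SPAD-502)
pressed onto individual leaves — accurate but slow, contact-based and
pointwise. Hyperspectral imaging offers a non-destructive alternative: a
line-scan camera records a full visible/near-infrared reflectance spectrum
(here 387-1003 nm in 231 bands) at every pixel, and chlorophyll absorption
leaves a strong, well-understood imprint on that spectrum — deep
absorption around 430-460 nm and 650-680 nm, a sharp "red edge" rise near
700-750 nm, and a high NIR plateau.

`chlorospec` implements an end-to-end pipeline from raw camera counts to a
SPAD estimate per plant:

1. **Radiometric calibration** of raw digital numbers against white-panel
   and dark-current reference frames,
   \(R = (I_{raw} - I_d)/(I_w - I_d)\).
2. **Band trimming** to the low-noise 437-919 nm window (180 of 231
   bands on the default grid).
3. **Foreground segmentation** (excess-green score, Otsu threshold,
   morphological cleanup) and **ROI mean-spectrum extraction**.
4. **Min-max scaling** of each mean spectrum to \([0, 1]\).
5. A **1-D convolutional regression network with a spectral attention
   gate**, trained with Adam under a cosine-annealed learning rate.
6. Classical comparators — PLSR and random forest on the full spectrum,
   with optional successive-projections (SPA) wavelength selection and
   first-derivative (FDR) preprocessing — under the same five-fold
   cross-validation harness.

Because greenhouse imaging campaigns are rarely public, the package ships
a synthetic-data module that generates labelled spectra and full scenes
with known ground truth; every stage of the pipeline is tested against it.

## Radiometric calibration

`calibrate_reflectance()` applies the two-point correction exactly and
deliberately does **not** clip the result to \([0, 1]\): photon and
read-out noise can push individual pixels slightly past the white level,
and discarding that information is a preprocessing decision, not part of
the physical correction. The correction is invariant under any common gain
applied to cube and references, which the tests verify to machine
precision. Reference frames may be full-frame or single-line
(`1 x width x bands`) recordings — line-scan instruments usually store one
calibration line per cross-track pixel — and line references are broadcast
down the scan axis.

The default grid is equally spaced: 231 bands across 387-1003 nm, i.e.
roughly 2.68 nm per band. Trimming uses a closed interval, so the
437-919 nm window retains exactly 180 bands on that grid; this closed-
interval convention is part of the package contract.

## Segmentation and spectrum extraction

Plant-versus-background separation uses the excess-green index
\(2G - R - B\) with the three channels taken from the reflectance planes
nearest 550, 660 and 470 nm. An earlier design scored greenness on the
8-bit RGB preview produced by `synthesize_rgb()`, but the preview
stretches each channel independently to 0-255; on a dark-background scene
that stretch maps the plant to full intensity in *every* channel and the
green excess vanishes. Scoring on reflectance avoids this while keeping
the preview available for inspection.

The greenness map is thresholded with `otsu_threshold()` — the classical
histogram search maximizing between-class variance
\(\sigma_b^2(t) = w_0 w_1 (\mu_0 - \mu_1)^2\) over 256 equal-width bins
spanning the observed range. The threshold is computed in-package (and is
checked against an exhaustive brute-force search in the tests) because the
installed image library's variant uses a non-standard class split and
reports bin midpoints, which breaks exact agreement with the textbook
definition; morphology (disc-kernel opening then closing, radius 2 pixels
by default) and connected-component labelling still come from `EBImage`.
After cleanup the largest component is kept. An empty mask is an error,
not an empty spectrum.

`mean_roi_spectrum()` is a plain arithmetic mean over foreground pixels
per band; it commutes with band trimming, and background values have
provably no influence.

## The synthetic forward model

`generate_spectrum()` maps a SPAD value to reflectance as

\[ r(\lambda) = b(\lambda) \;-\; d \cdot s \sum_j
   \exp\!\left(-\frac{(\lambda - c_j)^2}{2\sigma_j^2}\right), \]

where \(b(\lambda)\) is a flat visible baseline (0.55) rising through a
logistic red edge (centre 715 nm, scale 16 nm) to an NIR plateau (0.85),
the absorption centres \(c_j\) are 450 and 662 nm (widths 22 and 28 nm),
and the depth grows linearly with SPAD at \(d = 0.009\) per unit. Additive
Gaussian noise (sd 0.01 in reflectance units, emulating the residual noise
of an ROI-averaged spectrum) is applied per band, and the result is
clipped to \([0, 1]\). Scenes add an elliptical two-lobe "lettuce blob" on
a dark background, spatially flat references with a smooth spectral
illumination profile, and per-pixel noise.

Defaults were chosen once, on physiological grounds: SPAD labels are drawn
uniformly from 15-50 (the realistic range of SPAD-502 readings on green
leaves; the range is a stand-in, since campaign-specific SPAD
distributions vary), the absorption depth keeps reflectance away from the
clipping boundaries over that whole range (so the SPAD-to-spectrum map
stays strictly monotone), and the default dataset size is 478 samples,
the size of a typical single-variety greenhouse campaign. The linear
depth-per-SPAD mapping is the simplest identifiable choice.

What the generator deliberately does *not* emulate: radiative-transfer
realism (PROSPECT-class leaf optics), multiple pigments, specular
highlights, canopy geometry, red-edge position shifts, or
instrument-specific stray light. Passing the recovery benchmarks therefore
demonstrates that the pipeline's machinery is correct and well-calibrated,
not that any particular accuracy will be reached on real campaign data.

## The attention network

The network consumes the 180-band min-max-scaled mean spectrum:

* **Spectral attention (squeeze-and-excitation) gate.** The input is a
  single-channel sequence, so bands play the role of channels: the
  global-average-pooled descriptor of each band's singleton spatial extent
  is the band value itself. Two fully connected layers
  (180 → 45 → 180, ReLU between, bottleneck ratio 4) followed by a sigmoid
  produce a per-band weight in \((0,1)\) that rescales the spectrum. With
  all gate parameters at zero every weight is exactly 0.5. The gate is the
  data-driven analogue of wavelength selection: `get_attention_weights()`
  exports the mean gate vector for plotting, and on synthetic data the
  trained gate weights the chlorophyll absorption window above a flat,
  label-independent NIR window.
* **Stem.** One convolution (kernel 7, stride 2, asymmetric same-padding)
  followed by average pooling (kernel 3, stride 3): 180 → 90 → 30, exactly
  1/6 of the input length for any input divisible by 6.
* **Inception block.** Four parallel branches on the 16-channel stem
  output — convolutions with kernels 1, 3 and 5, plus average pooling
  (kernel 3, stride 1) followed by a 1x1 convolution — each 16 channels,
  concatenated to 64.
* **Head.** Flatten, a 64-unit fully connected layer, ReLU, and a single
  linear output.

Channel widths, the stem kernel, the bottleneck ratio and the head width
are package defaults, declared in `model_config()`; the strides (2 and 3),
the kernel set \{1, 3, 5\} plus pooling branch, and the two-layer head are
structural. With `attention = FALSE` the gate is ablated to the identity,
giving the plain 1-D Inception comparator; the two variants differ by
exactly the 16,425 gate parameters (142,186 vs 125,761 in total).

### Training

Loss is mean squared error plus an L2 penalty (\(10^{-4}\)) on weight
matrices (not biases). Optimization is Adam (\(\beta_1 = 0.9\),
\(\beta_2 = 0.999\)) at a peak learning rate of \(10^{-4}\), batch size 6,
under cosine annealing to zero with warm restarts every 200 epochs;
the default budget is 500 epochs. Two further choices matter:

* **Response standardization.** SPAD values are internally centred and
  scaled (training-fold statistics only) during optimization and
  predictions are mapped back to SPAD units. With a peak step size of
  \(10^{-4}\) per parameter, raw responses of magnitude 15-50 would be
  unreachable within realistic epoch budgets; standardization makes the
  optimization well-scaled without touching the advertised loss.
* **Augmentation.** Each training minibatch receives fresh offset/slope
  jitter — a multiplicative factor \(a \sim U(0.95, 1.05)\) and an
  additive offset \(b \sim U(-0.1\sigma, 0.1\sigma)\), with \(\sigma\) the
  per-spectrum standard deviation. Validation folds are never augmented,
  and the jitter draws come from the training RNG stream, so a run is
  bit-reproducible given the configuration seed.

The forward/backward passes are implemented in vectorized R (patch-matrix
convolutions); gradients are verified against central-difference numerics
in development, and the layer shapes are asserted in the tests. There is
no early stopping: training history (train/validation MSE in SPAD², and
the learning rate) is recorded per epoch instead.

## Baselines

* **PLSR** delegates to `mixOmics::pls` (regression mode). The component
  count is tuned per training split by inner five-fold cross-validation
  (ceiling 15), exploiting that one fit yields predictions at every
  smaller component count.
* **Random forest** delegates to `randomForest` with 1500 trees by
  default — the value a tree-count grid search settles on for this kind of
  spectra — with other hyperparameters at package defaults (p/3 variables
  per split, unlimited depth). `grid_search()` is available when the
  tree-count (or component-count) search should be re-run explicitly.
* **SPA** is implemented in-package (no installed package provides it):
  from every candidate start column a chain is grown by repeatedly adding
  the band with maximal residual norm after projection orthogonal to the
  span of the already-selected bands; every chain prefix with size in
  3-15 is scored by five-fold cross-validated calibration RMSE and the
  best subset wins. The default calibrator is PLSR with as many components
  as selected bands, which for these small well-conditioned subsets equals
  least squares and is computed as such (this keeps the 180-start scoring
  loop inexpensive); a custom calibrator function can be supplied. Whether
  such selection should use the response at all is a modelling choice; the
  package implements the standard calibration-guided variant.
* **FDR** is the first derivative of the *unscaled* mean spectrum with
  respect to wavelength (central differences, one-sided at the ends),
  followed by min-max scaling of the derivative vector. The
  derivative-then-scale order is a declared convention; the reverse order
  is also defensible but conflates the two normalizations.

Within each cross-validation split the SPA wavelengths are shared between
the PLSR and RF arms: both arms re-run the selection on the same training
data with the same internal seed, which yields identical subsets without
any cross-arm state.

## Evaluation protocol

`kfold_split()` shuffles and partitions into near-equal folds (478 → 96,
96, 96, 95, 95). `compute_metrics()` reports
\(\mathrm{RMSE} = \sqrt{\tfrac1n \sum_i (y_i - k_i)^2}\),
\(\mathrm{NRMSE} = \mathrm{RMSE}/\bar y\) (mean-normalized, not
range-normalized) and
\(R^2 = 1 - \sum_i (y_i - k_i)^2 / \sum_i (y_i - \bar y)^2\).
`run_cv()` produces the per-fold table plus an unweighted `"Average"` row
and attaches the held-out predictions for scatter plots. Every
data-dependent choice — augmentation, response standardization, PLSR
component tuning, SPA selection — happens strictly inside the training
folds; a poisoning test (perturbing validation labels) verifies that the
trained parameters are bit-identical.

Min-max scaling is per-sample (each spectrum rescaled independently), so
applying it before the fold split leaks nothing; a dataset-wide per-band
variant exists behind `scope = "band"` for users who want it, but it
couples samples and is not used by the harness.

## Problem sizes and numerical choices

The shipped benchmarks use the study-scale dataset of 478 samples with
five folds. For the recovery benchmark the network is trained 100 epochs
per fold (about 75 s per fold in this implementation) — a budget at which
the synthetic task is already fit to held-out \(R^2 > 0.9\); the attention
versus plain comparison in the test suite runs on a reduced single split
(160/40 samples, 60 epochs, three seeds) and is reported rather than
gated, since the margin between the two variants on easy synthetic data is
small relative to seed noise. Unit tests use 60-200 samples.

Degenerate inputs are errors, not silent results: constant spectra cannot
be min-max scaled or Otsu-thresholded, a constant ground truth has no
\(R^2\), a zero calibration denominator names the offending pixel and
band, and an empty segmentation mask aborts extraction. Ties in the Otsu
search go to the lowest maximizing cut; ties in grid search go to the
simpler model.

## Known limitations

* The synthetic generator is a structural stand-in; absolute accuracies on
  it say nothing about accuracy on real greenhouse data.
* The network implementation is CPU-only, single-threaded R; it is sized
  for ~180-band spectra and a few hundred samples, not for pixel-level
  training.
* SPA evaluates all start columns exhaustively; for much wider spectra
  the scoring loop grows quadratically in band count.
* The ENVI reader handles the common flat-binary interleaves and numeric
  types only (no compression, no BIP tiling, little-endian only).
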