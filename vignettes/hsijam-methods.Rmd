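---
title: "Methods: hyperspectral sugar-content regression in apple jam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral sugar-content regression in apple jam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sugar concentration (soluble solids content, % w/w) determines the taste,
shelf life and legal compliance of fruit preserves; reference assays
(refractometry, titration, chromatography) are destructive or slow.
`hsijam` implements a non-destructive alternative: visible/near-infrared
(VNIR, 400–1000 nm, 204 bands) hyperspectral imaging of jam samples,
followed by spectral feature extraction and regression. The package covers
the full chain — raw intensity cubes with white/dark reference frames,
reflectance calibration, spectral-angle segmentation, grid feature
extraction, leakage-aware splitting, and three regression models — plus a
synthetic scene generator so that every stage is runnable and testable
without camera data.

## The acquisition model and what the generator emulates

The campaign the package targets is factorial: 8 apple cultivars x 11
sugar levels (25–75 % w/w in 5 % steps) x 3 layer thicknesses (0.5, 1 and
2 cm) imaged from 6, 7 and 7 views respectively — 1760 captures, 88
distinct (cultivar, concentration) samples. `acquisition_design()` encodes
this layout and `enumerate_design()` expands it; camera distance
(20/30/40 cm) is carried as per-view metadata only, and views are opaque
indices: nothing downstream depends on which angle a view used, only on
the counts.

`spectral_model()` builds, per cultivar, a smooth reflectance baseline
with the empirical VNIR jam shape: a pigment-absorption dip with a local
minimum inside 400–500 nm and elevated reflectance across 700–900 nm,
with deterministic per-cultivar variation in level, dip position and
shoulder height. Added sugar perturbs the baseline through a compactly
supported Hann bump over 780–960 nm whose amplitude is
`sugar_magnitude * sugar_pct / 100` (default peak amplitude 0.12 at 100 %
sugar, i.e. 0.03–0.09 across the 25–75 % range). Two properties are
deliberate:

* the expected spectrum is *strictly monotone* in sugar at the affected
  bands and *identical* outside them, so recovery experiments have a
  well-defined signal; and
* the affected window lies entirely above 700 nm, outside the visible
  range, so broadband RGB features derived from the same scenes are blind
  to the sugar signal by construction. This realises the
  RGB-versus-hyperspectral contrast as a controlled experiment.

Sensor noise is i.i.d. additive Gaussian per band on reflectance,
`noise_sd = 0.01` by default — about 1 % of full-scale reflectance, a
realistic magnitude for a calibrated pushbroom VNIR camera at desk
integration times. `render_scene()` places a centred jam ellipse
(~38 % of the frame) on a bright near-flat "white dish" background and
synthesises the sensor side: a smooth per-band illumination/gain curve, a
dark-current spectrum `D`, white frame `W = D + gain`, and raw intensity
`I = D + R (W - D)` — so white/dark calibration inverts the construction
exactly and the whole chain can be validated to floating-point precision
at `noise_sd = 0`.

What the generator does *not* emulate — and what passing tests therefore
do not show about camera data: thickness-dependent optics (thickness is
metadata only), specular highlights, spatially correlated illumination
error, camera point-spread, or genuine resolution changes across the three
distances. The default frame is 64 x 64 px rather than the camera's
512 x 512: features are means over segmented pixels, so they are
insensitive to frame size, and desk-scale frames keep the full pipeline in
seconds per capture. Both choices are configurable.

## Calibration

`calibrate()` computes `R = (I - D) / (W - D)` with a denominator guard
`eps = 1e-6`; any pixel with `W - D <= eps` at any band is flagged in an
invalid-pixel mask and excluded from segmentation. The guard makes the
known failure mode of an imperfect white reference — overexposed areas
masquerading as dark regions — explicit rather than silent. Reflectance is
clipped to `[0, clip_max]` with `clip_max = 2`: values slightly above 1
are physical where the sample outshines the reference dish, so clipping at
1 would bias, while an upper bound contains artifacts. References may be
per-band spectra (broadcast spatially) or full per-pixel frames.

## Segmentation and features

Jam pixels are found with the spectral angle mapper:
`theta = arccos(p.r / |p||r|)` against a reference spectrum `r`, threshold
0.2 rad, *inclusive* comparison (a boundary pixel at exactly 0.2 rad
counts as jam; the convention is stated once and tested). The reference is
the per-band median of a seed region, by default the central 10 % x 10 %
patch — acquisitions centre the sample on the dish, and the median makes
the reference robust to isolated outliers; the region is overridable.

The mask's tightest bounding box is shrunk by a 10 % per-side margin
(`floor(fraction * dimension)` pixels, so coordinates stay integral and
reproducible) and subdivided into g x g grids, g = 1..5. Cells partition
the box exactly; when a dimension is not divisible by g the remainder
pixels go one each to the leading rows/columns — any fixed rule works,
this one is the simplest to verify by brute force. Each cell contributes
the mean spectrum of its segmented pixels, normalised to unit Euclidean
length; cells with fewer than `min_pixels = 5` segmented pixels are
dropped with a logged reason, since a mean over a handful of pixels is
noise-dominated. All pixel coordinates in the package are 0-based,
half-open intervals.

## Datasets and leakage-aware splits

Records (one row per subregion: `band_0001...`, sugar, cultivar, image
index, grid position, thickness, view) are materialised one table per grid
configuration, written as RFC 4180 CSV with 15 significant digits.

Two splits are implemented, both keyed on units coarser than the record so
that no image's subregions ever straddle folds (asserted on every split):

* **cultivar split** — 6 cultivars train, 1 validates, 1 tests
  (75 / 12.5 / 12.5 % of cultivars): evaluation on wholly unseen apple
  varieties;
* **concentration split** — every cultivar trains, but specific
  (cultivar, concentration) cells are held out. The default map assigns a
  deterministic rotating pattern (start offset 3(i-1), step 4, modulo 11,
  for cultivar i) of 2/2/2/2/2/2/1/1 test and 2/2/2/2/1/1/1/1 validation
  concentrations per cultivar: 14 test + 12 validation of the 88 cells,
  i.e. 70.5 / 15.9 / 13.6 % to one decimal. The published table of
  held-out cells is not machine-readable from text, so the package ships
  this reproducible stand-in with the same marginal fractions, both in
  code (`default_holdout_map()`) and as YAML
  (`inst/extdata/holdout_default.yaml`); any other map can be supplied.

Which cultivar validates versus tests is a user argument with a seeded
random fallback, since no canonical assignment exists.

## Regression models

All three models share one contract: min-max scaling of features and
targets fitted on the *training fold only* (the scaler records its
provenance and every trainer asserts it — fitting the scaler on train+test
is a leakage bug this design makes impossible to hit silently), training
on scaled targets, predictions mapped back to % sugar.

**SVM** — epsilon-insensitive support vector regression, RBF kernel,
C = 110, epsilon = 0.1, gamma = 0.01, via `e1071`. Gamma is the literal
kernel coefficient, not a data-driven heuristic. **XGBoost** — squared
error objective, learning rate 0.10, depth 5, column subsampling 0.95, up
to 400 rounds, early stopping after 40 rounds without validation RMSE
improvement, via `xgboost`, single thread for determinism.

**1D ResNet** — authored in this package in base R: im2col convolutions
as BLAS matrix products, batch normalisation, ReLU, dropout (p = 0.1),
Adam (lr 1e-3, weight decay 1e-4), mean-absolute-error loss on scaled
targets, at most 30 epochs with patience-5 early stopping that restores
the best-validation weights; "improve" means a strict decrease by at
least 1e-6, avoiding float-noise non-termination. The architecture: a
custom-padded stem convolution (pad `floor(k/2)` left,
`k - 1 - floor(k/2)` right, so stride-1 convolutions preserve length for
*any* kernel size — the reading under which custom padding is actually
necessary, since odd kernels with symmetric padding need nothing custom),
then 8 residual blocks of conv-BN-ReLU-dropout-conv-BN plus skip and
final ReLU. Every second block convolves at stride 2 and doubles the
filter count (spatial lengths 204 -> 102 -> 51 -> 26 -> 13); its skip is a
1 x 1 stride-2 projection with BN, the standard shape-compatible choice.
Global average pooling and a single dense unit close the network.

Unstated architectural constants are explicit config with defaults: stem
kernel 7, block kernels 3, dropout 0.1, base filters 16. Sixteen base
filters (doubling to 256 by the last block) is a deliberate capacity
choice for 204-band spectral vectors on CPU: in this implementation a
batch-64 training step at 32 base filters costs ~4x more for no
measurable gain in recovery accuracy on unit-norm mean spectra, whose
information content is far below that of the image patches residual
networks were sized for. `resnet_config(base_filters = 32L)` restores the
heavier network. Gradients are verified against numerical differentiation
in the test suite, and the parameter count against an independent
arithmetic walk of the architecture.

One master seed fans out (via the seeded RNG) to weight initialisation,
shuffling and dropout, making training bit-reproducible.

## Evaluation

`regression_metrics()` implements r2 = 1 - SS_res/SS_tot (the standard
definition), RMSE and MAE; `per_class_mae()` profiles error by sugar
level. `run_sweep()` crosses models x grids x (ResNet batch sizes) x
independent runs, retains per-run rows, and appends arithmetic-mean
aggregate rows — the mean, rather than the best, of repeated runs is
reported, with per-run values kept for dispersion. `rgb_vs_hsi()` runs the
identical sweep on hyperspectral and RGB tables from the same scenes and
pairs the aggregates. RGB features are boxcar means over 400–500 /
500–600 / 600–700 nm — the synthetic stand-in for a colour camera, since
no separate RGB sensor exists here.

## Problem sizes used by the tests and acceptance script

The shipped experiments run at desk scale, chosen once: recovery uses the
full 8 cultivars x 11 levels at 2 views (176 captures, 64 x 64 px,
`noise_sd` 0.01), the 2 x 2 grid table (704 records), the concentration
split, SVM, and the ResNet at batch 32 — batch sizes at the small end of
the sweep give more optimiser steps per epoch, which matters at a few
hundred training records. The RGB-versus-HSI experiment uses 4 cultivars
x 11 levels x 1 view at 48 x 48 px. Under these conditions the SVM
reaches validation R^2 ~ 0.97 and the ResNet ~ 0.91–0.93 (seed-dependent),
and the RGB arm collapses to R^2 ~ 0, reproducing the qualitative
hyperspectral-versus-RGB separation. These sizes are statements of the
experiments shipped, not of the method's limits; all are parameters.

## Numerical choices and degenerate inputs

* SAM cosine clamped to [-1, 1] before `acos`; zero spectra are an error,
  not NaN.
* Empty masks, margin-collapsed boxes, grids finer than the box, constant
  scaler columns, missing validation folds, and batch sizes exceeding the
  training set all raise early, named errors.
* ENVI I/O: band-interleaved-by-line, 32-bit float, little-endian by
  default (the camera's native precision); BIL/BIP/BSQ and 64-bit float
  are accepted on read and write, and the header's `bands` entry is
  validated against its wavelength list.
* Reflectance clipping is idempotent; the invalid-pixel mask is exactly
  the set `{W - D <= eps}`.

## Known limitations

The generator's i.i.d. noise and rigid geometry make segmentation easier
than on real scenes; SAM thresholds that are comfortable here may need
retuning on camera data. Thickness and view angle carry no optical
effect, so models cannot be probed for robustness to them. The default
hold-out map reproduces the published marginal fractions but not the
exact published cell assignment. Hyperparameter search is out of scope:
the classical models run at their published optima only.
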