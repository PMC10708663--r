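---
title: "Quantitative hyperspectral imaging of medicinal material: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative hyperspectral imaging of medicinal material: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsiQuant)
```

# Overview

`hsiQuant` estimates five quality attributes of *Salvia miltiorrhiza* —
salvianolic acid B, dihydrotanshinone I, cryptotanshinone, tanshinone IIA
(mass fractions) and moisture content — from visible/near-infrared
hyperspectral images of plates of sample segments. The instrument grid is
128 bands from 380 nm at 5.38 nm sampling (10 nm optical resolution is
stored as metadata only: the data grid follows the sampling interval).
This vignette explains the models, the tunable parameters, the synthetic
data generator, and the design choices made where the design was open.

# Radiometric model

Raw counts are converted to relative reflectance by the standard two-point
calibration against a whiteboard frame $W$ and a dark-current frame $D$:

$$R = \frac{I - D}{W - D}$$

No published equation accompanies the named whiteboard/blackboard
procedure, so the package adopts this universal convention. The
denominator is floored at $10^{-6}$ and the output clipped to $[0, 1.5]$
to tolerate specular pixels; absorbance is $A = \log_{10}(1/\max(R,
10^{-4}))$, the floor avoiding infinities in dead pixels. Calibration
followed by the absorbance transform is monotone decreasing in the raw
counts, which the test suite asserts on random frames.

# Segmentation

The mask procedure is not specified by the source description beyond
"mask, region of interest, average"; the package thresholds the band
nearest 850 nm — tissue/plate contrast is strongest in the NIR — with
Otsu's method (fixed thresholds can be supplied), applies a 3×3 binary
opening (opening is idempotent, so re-masking a mask is a no-op), labels
connected components in row-major discovery order and drops components
below `minArea` (default 50 px). Both one-spectrum-per-plate (default)
and per-segment extraction are provided, because it is not stated whether
the original analysis pooled the 30 segments of a plate or fed sub-images
separately.

# Calibration models

**PLSR** is a NIPALS implementation (the engine is shared with the CARS
and UVE selectors so regression-coefficient conventions are identical).
Latent-variable count defaults to 5-fold cross-validated RMSE over 1–15.
At full rank PLSR equals ordinary least squares, which the tests verify
against `lm.fit` at $10^{-8}$.

**ε-SVR** (Vapnik ε-insensitive loss, RBF kernel) is fit per target via
`e1071::svm`; hyperparameters default to $C = 10$, $\gamma = 1/p$,
$\varepsilon = 0.1$ with an optional seeded grid search, since no values
are published.

**RBFNN** uses seeded k-means centres, widths equal to the mean distance
to the two nearest other centres (a standard heuristic; the width rule is
unpublished), Gaussian activations $\exp(-d^2/2r_j^2)$ of the Euclidean
distance to each centre, and a ridge-regularized linear output layer.
With centres at all training points and ridge $\to 0$ the network
interpolates, which the tests assert at $10^{-6}$.

All multi-target models standardize each target independently and invert
the transform at prediction, so metrics are computed in mass-fraction
units.

# Wavelength selection

**CARS**: `nRuns` (default 50) Monte-Carlo iterations, each fitting PLS
on an 80% subsample, ranking bands by $|b|$, enforcing the exponentially
decreasing retained fraction $r_i = a e^{-k i}$ calibrated so $r_1 = 1$
and $r_N = 2/p$, then resampling among survivors proportionally to
$|b|$; each iteration's subset is scored by cross-validated RMSE and the
minimizer wins. A two-variable floor prevents collapse. **SPA** appends
the band with maximal residual norm after projection onto the orthogonal
complement of the chosen columns; the subset size is chosen by
cross-validated least squares, and on RMSE ties the shorter chain wins
(so a band spanning the response is selected alone). **UVE** appends $p$
uniform noise bands of relative amplitude $10^{-10}$, computes
leave-one-out PLS coefficient stabilities $c_j = \bar b_j / s_{b_j}$, and
eliminates real bands whose $|c_j|$ does not exceed the noise maximum.
Ranking ties always break to the lower band index, making every selector
bit-reproducible under its seed.

# The SE-ResNet regressor

The reference architecture is a 7×7/stride-2/padding-3 stem convolution
with batch normalization, a 3×3/stride-2 max-pool, four stages of
SE-residual blocks repeated (3, 4, 23, 3) times, global average pooling,
and a 2048 → 256 → 5 fully connected head. Block internals are not
published; the only standard layout consistent with those counts and a
2048-wide head is the bottleneck family (1×1 reduce, 3×3, 1×1 expand)
with stage widths (256, 512, 1024, 2048), which the package adopts,
with SE reduction ratio 16. Each block's squeeze-and-excitation unit
computes per-channel global averages, passes them through a
$C \to C/16 \to C$ bottleneck with ReLU then sigmoid, and rescales the
block output channel-wise; pinning the gates to 1 (`seEnabled = FALSE`)
recovers a plain residual network for ablations. The printed max-pool
padding of 3 is geometrically degenerate for a 3×3 window, so the default
is padding 1 with the printed value selectable.

How the cube feeds the stem is also unspecified; the package takes the
minimal-assumption reading: the input is a reflectance patch (foreground
bounding box, bilinearly resized to a configurable spatial size) with
the 128 spectral bands as input channels.

Training is the package's own protocol (none is published): MSE on
z-scored targets, Adam with a cosine-annealed learning rate (default
initial $2\times10^{-3}$ over 120 epochs), batch 32, seeded shuffling,
optional early stopping on a validation fraction. Input patches are centred per feature
(pixel × channel, across the training samples) to remove the static
plate/segment geometry, then scaled per spectral channel by the pooled
deviation standard deviation, with the statistics stored in the model
and reused at prediction. The per-feature centre exposes the small
between-sample concentration signal that would otherwise be dwarfed by
the fixed spatial contrast; scaling per channel (rather than per
feature) avoids amplifying signal-free background pixels to unit
variance. Batch 32 matters for the same reason: with strong
between-sample structure, batch-norm statistics over smaller batches
jitter enough to stall the final phase of optimization. Optional
input-noise augmentation and decoupled weight decay are available in
`TrainConfig` but default to off — on these data the residual test
error of a single network is dominated not by noise memorization but by
stochastic training variance: residuals of networks trained from
different seeds are nearly uncorrelated. The package therefore provides
`trainEnsemble()`, a standard deep ensemble over initialization seeds
whose averaged predictions remove most of that variance; the simulation
study uses four members. After optimization the batch-norm
statistics are replaced by a cumulative average over the training set —
with deep stacks of normalization layers the exponential moving average
lags the converged batch statistics enough to distort inference, and the
refresh removes that bias. The implementation is plain R over BLAS
(im2col convolutions with hand-written backward passes); all gradients
are verified against numerical differentiation in the test suite.

The desk profile `deskArchitectureSpec()` — blocks (1, 1, 2, 1), widths
(64, 128, 256, 512), 8×8 input patches, 512 → 64 → 5 head — is the
package's CPU-scale configuration used in the simulation study and
tests; the reference profile is available for full-scale work. Patches
are produced by area-averaged (block-mean) downsampling of the
foreground bounding box, which averages per-pixel noise instead of
aliasing it. Capacity matters more than size here: halving the desk
widths costs far more held-out accuracy than the parameter count
suggests, while the ensemble controls the variance that the extra
capacity would otherwise add.

# Evaluation

Kennard–Stone partitioning seeds the calibration set with the two most
distant samples (Euclidean, on the preprocessed mean spectra) and then
adds max-min-distance samples until $\lfloor 4n/5 \rfloor$ are selected;
with 187 samples this yields 149 calibration and 38 test samples, and
ties break to the lowest sample index. Metrics follow

$$\mathrm{RMSE} = \sqrt{\tfrac{1}{n}\sum_i(\hat c_i - c_i)^2}, \qquad
R^2 = 1 - \frac{\sum_i(\hat c_i - c_i)^2}{\sum_i(c_i - \bar c)^2},$$

where $\bar c$ is the mean of the measured values — the printed form of
the $R^2$ denominator elsewhere uses the estimates' deviations, but the
accompanying variable definitions support the standard
measured-deviation convention implemented here.
$\mathrm{RPD} = \mathrm{SD}_{cal}/\mathrm{RMSEP}$ uses the sample (n−1)
standard deviation, with the usual five interpretation bands (<1.5
limited; 1.5–2.0 distinguishes high/low; 2.0–2.5 approximate; 2.5–3.0
good; >3 excellent). $\mathrm{RER} = (Y_{max}-Y_{min})/\mathrm{RMSEP}$
uses calibration-set extrema: recomputing the published RER table from
the published content ranges and RMSEP values reproduces all five
reference values to 3 decimals only under that reading, which fixes the
convention. Cross-validation is seeded 5-fold on the calibration set
(the original scheme is unstated); out-of-fold predictions are pooled
before metrics are computed. RMSE is non-negative by construction; the
negative RMSEP/RER entries printed for the linear baseline in the source
table are arithmetic artifacts that the package does not emulate.

# The synthetic generator

No image data are deposited, so the generator emulates the *structure*
of the study, not the spectroscopy of the analytes:

* **Concentrations** are drawn from a truncated multivariate normal with
  means and bounds at the published calibration content ranges, e.g.
  moisture in [0.057, 0.085] with mean 0.071. Sampling standard
  deviations are $\min(\text{mean}-\text{min},
  \text{max}-\text{mean})/2.5$, so bounds sit ≥2.5 SD from the mean,
  truncation is rare, and the embedded 0.64 cryptotanshinone–tanshinone
  IIA correlation survives the rejection step essentially unattenuated
  (the tests recover it within ±0.05 at n = 2000).
* **Endmembers** are five synthetic absorptivity curves of 2–3 Gaussian
  peaks spread over 450–1000 nm (moisture near the 970 nm water band),
  each scaled so the mean concentration contributes ≈0.35 absorbance at
  its peak — without this, attributes whose mass fractions differ by two
  orders of magnitude would have wildly unequal signal.
* **Plates** are rendered at 80×96 px with a 5×6 grid of radius-5 discs
  (a down-scaled version of the 703×800 acquisition geometry, which is
  available via the config), per-pixel absorbance
  $A = \text{baseline} + (1+\text{field})\sum_k c_k \varepsilon_k$, a
  smooth multiplicative field of amplitude 0.05, reflectance $10^{-A}$,
  and raw counts $D + R(W-D) + \mathcal N(0, (0.01(W-D))^2)$. An optional
  quadratic absorbance term emulates the non-bilinear scattering regime
  that defeats linear models on real reflectance data; it is off by
  default.

What passing tests therefore show: the pipeline inverts its own forward
model, the deep regressor learns a smooth five-output mapping from
realistic plate images under noise, and every algorithmic contract holds.
What they do not show: performance on true tissue spectra, scattering
physics, or instrument artifacts beyond additive noise.

# Problem sizes and numerical choices

The simulation study in the acceptance tests uses 187 samples (149/38
after splitting) and a four-member desk-profile ensemble trained for
120 epochs at batch 32, seed 1 — sizes chosen so the whole suite runs
comfortably on a single CPU. Tolerances: metric oracles at $10^{-12}$, PLSR–OLS agreement at
$10^{-8}$, forward-model inversion at $10^{-6}$. Degenerate inputs are
contracts, not crashes: constant targets give intercept-only PLSR models
with a warning, zero-variance columns are floored with a warning,
empty masks warn and return zero segments, duplicate RBF centres floor
their widths.

# Known limitations

* The generator is linear in absorbance by design; with the nonlinearity
  switch off, linear baselines are nearly exact on noiseless data, so
  model rankings on synthetic data do not transfer to real tissue.
* The deep model is pure R; the reference-depth profile builds and runs
  but is intended for batch scoring, not training, at full image scale.
* ENVI I/O supports BSQ interleave only; sample tables travel as CSV.
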