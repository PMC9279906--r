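---
title: "Methods: hyperspectral canopy trait regression with canopyspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral canopy trait regression with canopyspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyspec)
```

## The problem

Biochemical quality traits of leafy crops -- soluble solids content (SSC,
in %, a refractometric sugar measure) and juice pH -- are normally measured
destructively: the plant is juiced and read on a refractometer and pH
meter. Vis--NIR hyperspectral imaging (here 400--1,000 nm, 256 bands)
offers a non-destructive alternative: a canopy's mean reflectance spectrum
carries pigment, structure and water signals that co-vary with such
traits, so a regression model can map spectrum to trait. `canopyspec`
implements the full chain from raw hypercube to trait prediction:

1. **Reflectance calibration** of raw digital numbers against white and
   dark references,
2. **canopy segmentation** by the spectral angle mapper (SAM) and
   extraction of the per-plant mean spectrum,
3. **chemometric pretreatments** (MWS, SG, FDR, SDR, WT),
4. **sample partitioning** (Kennard--Stone 2:1 plus a random 15%
   validation carve-out),
5. **CARS wavelength selection**,
6. **regression** by five multivariate baselines (PLSR, LWR, MLR, ANN,
   SVR) and two purpose-built neural regressors (Deep2D, DeepFC),
7. **evaluation** by $R^2$, RMSE and RPD on the three splits.

Every stage is exercised on synthetic canopy spectra with known structure,
because the emulated field campaign's data are not public. The synthetic
generator is first-class, tested code, not a fixture.

## Calibration

Reflectance is $R = (R_{raw} - R_d)/(R_w - R_d)$ per pixel and band, with
$R_w$ from a high-reflectance white panel and $R_d$ the sensor dark
current. Design choices:

* References may be per-column (sample x band) means -- the natural form
  for a push-broom line scanner, where each detector column has its own
  response -- or full cubes. 3-D references are collapsed to per-column
  means by default.
* Positions where $R_w = R_d$ carry no information and are masked `NA`
  rather than clipped or filled; downstream operations (mean spectra,
  SAM) exclude them.
* Reflectance is **not** clipped to [0, 1]: specular glint above 1 passes
  through, since clipping would bias canopy means downward.
* Calibrating an already-calibrated cube raises an error; silent
  double application would corrupt every downstream statistic.

ENVI BSQ is the canonical write layout; BIL and BIP are accepted on read.
All floats are written at 17 significant digits (CSV) or as 64-bit
little-endian binaries (cubes), so round trips are exact.

## Segmentation

SAM scores each pixel by the angle between its spectrum and a reference
endmember, $\theta = \arccos(\langle t, r\rangle / \|t\|\,\|r\|)$. The angle
is scale-invariant, which makes it robust to the strong illumination
differences between top and bottom canopy leaves that defeat plain
thresholding. A pixel is plant iff its minimum angle over plant endmembers
is below the threshold (default 0.10 rad, configurable -- interactive
workflows rarely record this number) and strictly smaller than its minimum
angle to any background endmember. Ties go to background: a conservative
mask keeps canopy spectra uncontaminated. The mean canopy spectrum
averages plant pixels only; including zeroed background pixels would scale
the mean by canopy fraction, confounding trait signal with plant size.

## Pretreatments

All pretreatments are per-sample row operations that preserve the band
count, so models are comparable across treatment arms.

| treatment | default parameters | rationale |
|---|---|---|
| MWS | window 5 | common Vis--NIR practice; edges use symmetrically shrunken windows |
| SG  | window 11, order 2 | preserves peak shape/width; edges use off-centre polynomial evaluation |
| FDR/SDR | forward differences, tail-padded | listed as distinct treatments from SG derivatives, so implemented as plain differences, unscaled by the (uniform) band spacing |
| WT  | db4, level 3, soft universal threshold | standard wavelet denoising defaults |

The wavelet transform is a periodized orthogonal DWT written in-package
(no wavelet package is available in the target environment); the universal
threshold is $\sigma\sqrt{2\ln B}$ with $\sigma$ from the median absolute
deviation of the finest details. Non-dyadic band counts are
reflection-padded and truncated after reconstruction; with thresholding
disabled the transform reconstructs its input to numerical precision,
which is unit-tested.

## Sample partitioning

Kennard--Stone picks a representative calibration pool by the max--min
rule: the two most distant samples seed the set, then each pick maximizes
the minimum Euclidean distance to the already-selected set. Ties break to
the lowest sample index, making the algorithm fully deterministic; it is
tested against an exhaustive brute-force implementation for all n up to 12.

`split_samples` rounds half away from zero: with n = 387 and a 2:1 ratio
the pool is 258; 15% of 258 is 38.7, so 39 validation samples leave 219
for calibration and 129 for prediction. The validation carve-out is the
only random step and is governed by an explicit seed; different seeds move
only the calibration/validation boundary, never prediction membership.
The multivariate arms split **after** pretreatment (the representative-
sampling step should see what the model sees); the deep arms split on raw
spectra, which is their entire premise.

## CARS wavelength selection

CARS is named after its selection pressure: wavelengths compete through
the absolute values of PLS regression coefficients. Each of N runs
(default 50) draws 80% of the samples, fits PLS1 on the surviving
wavelengths, then applies two eliminations: *forced selection* keeps the
top $\lceil r_i p\rceil$ wavelengths, where $r_i = a e^{-ki}$ decays from
$r_1 = 1$ to $r_N = 2/p$; *adaptive reweighted sampling* draws that many
wavelengths with replacement, weighted by coefficient magnitude, and keeps
the distinct survivors. A 5-fold cross-validated RMSE (PLS component count
chosen by inner CV, up to 10) is recorded per run and the minimizing run
defines the selection. All of this is seeded and replay-identical.

To avoid information leakage the cross-validation is restricted to
calibration samples: the pipeline pretreats, splits, runs CARS on the
calibration set only, and then applies the band subset to every split.

## Regression baselines

* **PLSR**: PLS1 via NIPALS, written in-package (shared with CARS) since
  no dedicated PLS package is available in the target environment; with
  all components on well-conditioned data it reproduces MLR coefficients
  to 1e-8 relative, and it is cross-checked against an independent PLS
  implementation where one is installed.
* **MLR**: ordinary least squares; rank-deficient designs (more bands
  than samples, collinear bands) fall back to the SVD minimum-norm
  solution with a warning and a flag.
* **LWR**: a lazy learner that projects queries into a global PLS score
  space (default 5 components), selects the nearest calibration samples
  there (raw band space is too collinear for a meaningful metric), and
  fits a tricube-weighted local linear model. Degenerate neighbourhoods
  fall back to a distance-weighted mean, which also gives the
  nearest-neighbour interpolation limit.
* **ANN**: a single-hidden-layer network (default 32 logistic units,
  linear output) fitted by BFGS through `nnet`; weights are initialized
  from an explicit seed, so fits are deterministic, and zero epochs
  returns the untouched initialization.
* **SVR**: epsilon-insensitive support vector regression through
  `e1071`. Inputs are not rescaled (reflectance bands share a scale);
  when epsilon exceeds the response range the dual is empty and the model
  degenerates to the constant $-\rho$, handled explicitly.

X and y are mean-centred internally for the linear families and
de-centred at prediction; this is invisible to the caller. Per-family
hyperparameters are deliberately exposed rather than fixed: the emulated
study tuned them on a validation set, and the grid runner does the same.

## Deep regressors

**Deep2D** maps the 256-band spectrum onto a 16 x 16 grid (row-major) and
applies three parallel same-padding convolutional branches -- kernel sizes
1, 3 and 5, 16 filters each, ELU activations -- whose outputs are
channel-concatenated, flattened and reduced to a scalar by linear fully
connected layers (default widths 32, 16, 1). The multi-scale block exists
because different absorption features have very different spectral
widths; parallel kernel scales capture narrow and broad features
simultaneously. How a 1-D spectrum should enter a 2-D convolution is the
largest design gap in this architecture family; the row-major 16 x 16
reshape is isolated behind `grid_shape` so alternatives (e.g. 1 x 256)
are a one-line config change. Branch filter counts and FC widths are
package defaults, declared rather than inherited from any reference.

**DeepFC** scales the feature dimension up before contracting it
(default 256 -> 512 -> 256 -> 64 -> 16 -> 1), with dropout (default rate
0.1) on the first two hidden layers and linear activations throughout, as
specified for this architecture; the composition is then affine, which is
verified in a test by composing the weight matrices explicitly. A
nonlinear override (`activation = "elu"`) is available.

Both are trained with Adam (lr 1e-4, batch 4 -- the tuned recipe), an
RMSE loss ($\sqrt{\text{batch MSE}}$; its gradient equals the MSE
gradient rescaled by $1/(2\,\text{RMSE})$, which Adam's normalization
absorbs) and MAE as the tracked metric. Early stopping retains the epoch
with minimal validation RMSE (default budget 500 epochs, patience 50).
Implementation is native R with im2col convolutions and explicit
backprop; with one input channel and a 16 x 16 grid the FLOP count is
small enough that BLAS-backed matrix products train either network in
about a minute per hundred epochs on one core.

Two visible conveniences, both config-flagged and never silent:

* `center_response` (default TRUE) trains on mean-centred responses and
  restores the offset at prediction. At learning rate 1e-4 an Adam step
  moves the output bias by about 1e-4 per update, so reaching a trait
  mean of ~3 from 0 would waste tens of thousands of steps. With
  `max_epochs = 0` nothing at all is applied and the model returns
  exactly as initialized.
* `standardize_input` (default FALSE): raw reflectance is the intended
  input path.

## Evaluation

$R^2 = 1 - \sum(y_p - y_r)^2 / \sum(y_r - \bar y)^2$ (the standard
denominator; a variant centring on predictions is available behind
`denominator = "predicted"` for comparison with sources that typeset the
formula that way), $RMSE = \sqrt{\sum(y_p - y_r)^2/n}$, and
$RPD = SD(y_r)/RMSE$ with the n-1 standard deviation. $R^2$ is not
clipped at zero. RPD is reported for the prediction set, using the
prediction set's own reference SD -- which split's SD to use is a genuine
ambiguity in practice, and the prediction set is the declared choice. The
identity $RPD \cdot RMSE = SD$ holds exactly and is asserted in tests.

## The synthetic generator

`generate_spectra` emulates a canopy trait-calibration campaign: 387
samples; an SSC-like trait (truncated normal, mean 3.1040, variance
0.5667, range 0.8750--5.8250) and a pH-like trait (mean 6.5945, variance
0.0074, range 6.3125--6.8175); spectra built from a deterministic
vegetation template (green peak near 550 nm, chlorophyll trough near
680 nm, red edge through 710--760 nm, NIR plateau, water dip near 980 nm)
minus trait-linked Gaussian absorption features, times multiplicative
scatter (sd 0.02), plus a linear baseline tilt (slope sd 0.005) and white
noise (sd 0.002 reflectance -- canopy means average thousands of pixels
and are smooth). The SSC-like trait drives NIR/water-feature depths; the
pH-like link is weaker, matching the general experience that pH is the
harder trait. A quadratic link option makes the depth a monotone but
curved function of the trait, giving nonlinear models a genuine edge over
linear ones; this is a property of the fixture, not a claim about any
crop. Truncated-normal sampling by rejection honours the printed range,
mean and variance simultaneously as closely as possible; the realized
variance after truncation is slightly below nominal.

What the generator does **not** emulate: radiative-transfer realism,
cultivar structure, growth stages, instrument striping, or temporal drift
of the white reference. Passing tests therefore demonstrate algorithmic
correctness and recoverability of known structure, not field performance.

## Benchmark problem sizes

The recovery benchmarks run at the study scale of n = 387 spectra with
256 bands. Training budgets are chosen so each benchmark trains in about
a minute: DeepFC 150 epochs with patience 30 on the linear-link
benchmark; Deep2D 60 epochs on the quadratic-link benchmark (whose
comparison partner, MLR with 256 bands and 219 calibration samples, is in
the pseudo-inverse regime and generalizes poorly). Wavelength-selection
recovery uses 200 samples x 200 bands with 10 informative bands at SNR
20 and the default 50 CARS runs. These sizes are the package's declared
test conditions; all are ordinary function arguments.

## Known limitations

* The ENVI reader supports the common core (BSQ/BIL/BIP, float types,
  wavelength blocks), not vendor extensions.
* CARS results depend on its Monte-Carlo defaults; selected band counts
  are not comparable across different run counts or CV folds.
* The deep stack is plain R: fine at spectral scale, not intended for
  image-to-image learning.
* DeepFC's all-linear default makes it an affine model with a particular
  optimization geometry; its value over PLSR on truly linear problems is
  regularization by early stopping, not expressiveness.
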