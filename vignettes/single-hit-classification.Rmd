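---
title: "Classifying single-hit diffraction patterns with spihits"
author: "spihits authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying single-hit diffraction patterns with spihits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In a single-particle-imaging (SPI) experiment at an X-ray free-electron
laser, individual aerosolized particles (here: virus-sized spheres, tens of
nanometres) are injected into a focused femtosecond X-ray beam. Each pulse
yields one detector frame. Most frames are empty or contain scattering from
several particles, droplets or debris; only *single hits* — frames whose
signal comes from exactly one particle — are useful for downstream
orientation determination and 3-D reconstruction. The class imbalance is
severe: roughly one single hit per two hundred frames that survive upstream
hit finding.

`spihits` implements the single-hit classification stage as a supervised
learning problem: a small set of frames is annotated at the start of an
experiment, a convolutional residual network is trained on it, and the
trained ensemble classifies the remaining (and future) stream. Around the
classifier the package provides the analytics used to judge a selection:
precision/recall/F1, intersection-over-union between selections,
angular-averaged intensity (PSD) curves with a fringe-contrast score, and
sphere-size estimation with band filtering. A synthetic diffraction
generator makes the whole pipeline testable end to end without any
experimental data.

## The classifier

The network is a pre-activation residual CNN. A standardized detector patch
(default $192 \times 96$ pixels, the live region of a half-dead two-panel
pnCCD) passes through an initial $3\times3$ convolution with 16 filters and
eight pre-activation residual blocks (batch norm → leaky ReLU → conv,
twice; identity shortcut, or a strided $1\times1$ projection where shape or
channel count changes). Downsampling is by strided convolution; the filter
count doubles at each downsampling up to 256. With the default plan — four
isotropic stride-2 steps and one anisotropic $(2,1)$ step — the final
feature map is $6\times6$, which global average pooling reduces to a vector
feeding a 2-logit linear head. The anisotropic step is the only way to
reconcile filter doubling capped at 256 with a $6\times6$ map from a
$192\times96$ input; it is placed last, where the map is already coarse.

Training uses Adam on class-weighted cross entropy, minibatches drawn with
replacement with the single-hit class over-sampled to a configured rate, and
a polynomial learning-rate schedule $\eta(t) = \eta_0 (1 - t/T)^{0.9}$.
Two configurations are provided:

* **MaxF1** — 2% singles per batch, equal class weights; optimizes the F1
  score, the natural model-selection criterion under imbalance.
* **moreSH** — 5% singles per batch, class weights 0.1/0.9
  (non-single/single); trades precision for recall when downstream stages
  need more candidate singles.

`hit_classifier()` trains a stratified five-fold cross-validation ensemble
and reports per-fold validation metrics as mean ± sd. At inference
(`predict()` / `ensemble_predict()`) the softmax outputs of all members are
averaged over the four mirror variants of each patch (none/horizontal/
vertical/both — 20 predictions per pattern for a five-member ensemble) and
thresholded at 0.5. A probability exactly at the threshold is labeled
non-single: with heavy imbalance, the conservative tie rule minimizes false
positives.

All network numerics (im2col convolution with BLAS matrix products, batch
normalization, the bilinear warp behind the augmentation) are implemented in
compiled code inside the package; the backward pass is verified against
central-difference numerical gradients in the test suite.

### Augmentation

Training-time augmentation covers random rotation, scaling, elastic
deformation, gamma, Gaussian noise, Gaussian blur, mirroring, random shift
and cutout. The geometric components are composed into a single displacement
field and resolved with one bilinear interpolation, so a rotated-scaled-
shifted-deformed patch is interpolated once, not four times. Magnitudes are
configurable per op; zero magnitudes give the identity. Defaults for
full-size patches: rotation ±15°, scale 0.85–1.15, elastic α≈100/σ≈10 px,
gamma 0.7–1.5, noise σ≤0.1 (standardized units), blur σ 0.5–1.5 px,
mirror p=0.5 per axis, shift ±10 px, one cutout box ≤32 px, with per-op
application probabilities between 0.15 and 0.5.

### Preprocessing

Patches are cropped from the live panel at a configurable anchor (default:
the region nearest the beam center, the highest-signal area) and
standardized as $(x-\mu)/\sigma$. The statistics are *computed from the
training crops* (masked pixels excluded) and stored with the ensemble; the
constants $\mu = 0.342$, $\sigma = 2.336$ known from the original
experiment's 20 000-frame training set are available as defaults for runs on
that data. Masked (dead-panel) pixels are zero-filled — zero is the
post-standardization mean proxy.

## Selection analytics

**F1 / precision / recall** use the standard definitions with the zero
convention for degenerate denominators (a selection with no true positives
scores 0).

**Intersection-over-union**: $\alpha = 100\,|A \cap B| / |A \cup B|$
percent, with a pairwise comparison matrix (`comparison_matrix()`) and a
multi-set generalization (`multiway_intersection()`). Percentages are
displayed rounded to the nearest integer; full precision is kept internally.

**PSD contrast**: the angular average of frame intensity over a selection is
binned in $q = 4\pi\sin\theta/\lambda$ (200 linear bins over the live-panel
range by default). On the normalized log$_{10}$ curve, after Savitzky–Golay
smoothing (7-bin window) and prominence pruning (2% of the curve's range),
local maxima are paired with the following minima and the contrast is the
mean difference over the first $N = 3$ pairs. Working on the normalized log
curve makes the score invariant to a global intensity scale; the choice of
log scale matches the order-unity contrast values conventionally reported
for these curves. `compute_psd(..., normalize_frames = TRUE)` additionally
gives every frame an equal vote by dividing it by its total intensity
first — essential when pulse fluence and particle volume spread frame
brightness over orders of magnitude, as a handful of bright frames otherwise
*are* the average.

**Particle sizing**: the PSD of a uniform sphere of radius $R$ has zeros at
the roots of $\tan x = x$ ($qR = 4.4934, 7.7253, \dots$), asymptotically
$\pi/R$ apart. `estimate_size()` fits the sphere intensity (free radius,
scale, flat background) to the per-pattern PSD by least squares, falling
back to the fringe-spacing relation $D = 2\pi/\overline{\Delta q}$ (median
spacing of successive minima — robust to one missed shallow minimum) when
the fit fails; patterns with no detectable fringes are *size-undetermined*
and are dropped, not errors. `size_filter()` keeps the inclusive 55–84 nm
diameter band, the expected virus size range. `estimate_background()` reads
the flat background off the high-$q$ region where particle signal is
negligible; subtraction clamps at zero.

## The synthetic generator

`generate_dataset()` emulates the statistical structure of a preprocessed
SPI hit stream:

* **Single hits** — one sphere's form-factor intensity, fluence-scaled,
  plus a flat background, Poisson-sampled per pixel, masked by the
  half-dead two-panel detector. Particle radii follow a peaked
  (truncated-normal) law inside the 27.5–42 nm band: an aerosolized virus
  population is close to monodisperse, and a peaked law is what lets a
  selection-averaged PSD retain several fringe orders. With probability
  0.2 a "single" is a contaminant of out-of-band size (30–130 nm diameter,
  excluding the band) — one dust grain or droplet is still a single
  particle, and these are what the size filter removes.
* **Non-single hits** — the squared modulus of the coherent sum of 2–4
  sphere amplitudes at random in-plane displacements of 100–600 nm,
  producing the interference stripes that cross the form-factor rings.
  Constituents draw contaminant sizes with probability 0.5: aggregates and
  debris are more heterogeneous than the injected sample, and it is this
  size heterogeneity that makes non-single admixture smear the fringes of a
  selection-averaged PSD (a coherent sum of *equal-size* spheres has the
  same expected angular average as a single sphere, only brighter). A
  further 10% of non-singles are background-only blanks — weak frames that
  survive hit finding.
* **Noise model** — per-pulse fluence is log-normal with σ = 0.5 (mean 1),
  positive and heavy-tailed like real pulse energies; photon counts are
  Poisson; the background is flat at 0.5 photons/pixel against a forward
  scattering scale of 2000 photons at the band-center radius, with
  amplitude scaling as particle volume.

What the generator does **not** emulate: icosahedral (non-spherical) form
factors, detector gain/dark structure, beam-center drift, structured
(water/jet) background, saturation, and real aggregate geometry (touching
particles). Passing tests therefore demonstrate that the pipeline's logic
and statistics behave as designed on sphere-like data — not that the
classifier reaches any particular accuracy on real detector frames.

Determinism: every generator and training entry point derives all its
randomness from explicit integer seeds; regenerating a dataset or re-running
a pipeline with the same configuration is byte-identical.

## Scaled study conditions

The package's demonstrations, tests and the acceptance script run on one CPU
core, so they use a reduced instance of the same design, fixed once:

* **Toy detector**: 64×64 pixels, lower panel dead, 270 µm pitch at 0.130 m
  and λ = 0.729 nm — the coarser pitch makes the 32-pixel live half span
  ~6 fringe periods of a 35 nm-radius sphere, preserving the geometry of
  the full-size problem.
* **Patches**: 32×16 crops; **network**: four residual blocks, 8→32
  filters, 4×4 final map (`model_config_small()`).
* **Data**: 4 000 training frames (100 singles / 3 900 non-singles — the
  same annotation budget as the full-scale recipe, at a 1:39 ratio) and a
  2 000-frame held-out stream (100 / 1 900).
* **Training** (`train_config_small()`): 5 folds × 2 000 iterations, batch
  32, and initial learning rate 7·10⁻⁴. The full-scale recipe pairs
  10⁻⁴ with 50 000 iterations; at a 25× shorter schedule that rate leaves
  the classifier stuck near the 2% base rate (with only ~0.6 single hits
  per batch, escaping the all-negative solution needs a stronger early
  push), and scaling the rate restores the same optimization regime.
  The scaled configuration keeps only the mirroring component of the
  augmentation pipeline: inference-time mirror averaging presumes models
  that treat mirrored inputs consistently, so mirroring must be seen in
  training, while the photometric and warp components are regularization
  against overfitting ~100 singles over 50 000 iterations — at 2 000
  iterations they cost more signal than they protect.
* **Recall comparison** (MaxF1 vs moreSH) uses 1 000-iteration single
  models over three seeds — enough budget to expose the sampling/
  loss-weighting effect on recall without retraining six ensembles.
* **PSD contrast experiment**: 150-frame pure-single selections vs 75/75
  mixtures, frame-normalized curves, 150 bins, prominence 1% (the toy
  detector's third fringe pair is shallow; at full scale the 2% default is
  appropriate).

## Numerical choices and edge cases

* Strict `>` at the 0.5 decision threshold (ties → non-single).
* IoU of two empty sets is undefined: an error from `iou()`, an `NA` cell
  in a comparison matrix.
* Degenerate metric denominators follow the zero convention.
* The learning-rate schedule is defined on $[0, T]$ and hits its endpoints
  exactly; iteration indices outside the range are errors.
* Batch-norm uses ε = 10⁻⁵ and running-statistic momentum 0.1; inference
  uses running statistics.
* Leaky-ReLU slope 0.01; He initialization.
* A non-finite training loss aborts with the iteration index rather than
  continuing silently.
* Extremum detection operates on the smoothed normalized log curve; a
  monotone curve yields an empty extremum set (not an error), while a
  contrast request that cannot find $N$ pairs reports how many it found.
* Pattern archives are a serialized container with named groups
  (`patterns`, `mask`, `ids`, optional labels/sizes/geometry); a missing
  group is reported by name. Geometry also round-trips through a YAML block
  for configuration files.

## Limitations

* The simulator's spheres are a deliberate simplification; real PR772-class
  particles are icosahedral, and real non-single hits include touching
  aggregates whose interference structure differs from well-separated
  spheres.
* The scaled network and patch size are sized for CPU demonstration runs;
  classifying real 192×96 patches at the full iteration budget is supported
  by the same code but is a GPU-day-scale computation in this
  implementation.
* PSD contrast is a fringe-visibility proxy for selection purity, not a
  reconstruction-quality metric; it is sensitive to the size dispersion of
  the selection, which is why size filtering precedes the most meaningful
  comparisons.

## A worked example

```{r example}
library(spihits)

g <- toy_geometry()
train_ds <- generate_dataset(sim_config(seed = 101), g,
                             n_single = 100, n_nonsingle = 3900)
test_ds <- generate_dataset(sim_config(seed = 202), g,
                            n_single = 100, n_nonsingle = 1900)

ens <- hit_classifier(train_ds, model_config_small(),
                      train_config_small("maxf1", seed = 7))
summary(ens)

preds <- predict(ens, test_ds)
precision_recall_f1(confusion_counts(test_ds$labels, preds$label))

sel <- predict(ens, test_ds, type = "selection", name = "cnn")
truth <- selection("truth", preds$id[test_ds$labels == 1])
comparison_matrix(list(sel, truth))
```

The same flow, with size estimation and filtering in between, is wrapped by
`run_pipeline()` and by the command-line front end in
`inst/cli/spihits.R`.
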