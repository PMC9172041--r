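# spihits

Single-hit diffraction-pattern classification for X-ray single-particle
imaging (SPI).

In an SPI experiment, individual nanoscale particles are injected into a
pulsed X-ray free-electron-laser beam and each pulse produces one detector
frame. Only *single hits* — frames whose scattering comes from exactly one
particle — feed the downstream orientation-determination and 3-D
reconstruction stages, and they are rare (roughly 1 in 200 frames after hit
finding). `spihits` implements this triage stage as a supervised-learning
problem, together with the analytics used to judge the resulting
selections:

* a **synthetic diffraction generator** — sphere form factors with
  concentric fringes, multi-particle coherent interference, Poisson noise,
  log-normal fluence jitter, flat background, a half-dead two-panel
  detector and a configurable 1:200 class ratio — so the whole pipeline is
  testable without experimental data;
* a **pre-activation residual CNN** (16→256 filters doubling at strided
  downsamplings, 6×6 final map from a 192×96 patch, global average pooling,
  2-logit head), trained with Adam on class-weighted cross entropy,
  minority-class over-sampling, on-the-fly augmentation and a polynomial
  learning-rate schedule, in stratified five-fold cross validation — all
  numerics written in compiled code inside the package and verified against
  numerical gradients;
* **ensemble inference** with mirror test-time augmentation (5 models × 4
  mirror variants = 20 softmax-averaged predictions per pattern, threshold
  0.5);
* **selection metrics**: precision/recall/F1 (the model-selection criterion
  under heavy imbalance), intersection-over-union
  α = 100·|A∩B|/|A∪B| with pairwise comparison matrices and a multi-set
  variant;
* **PSD analytics**: angular-averaged intensity curves in
  q = 4π sin θ/λ, a fringe-contrast score (mean max-minus-min difference
  over the first three extremum pairs of the normalized log curve),
  sphere-size estimation from form-factor fits or fringe spacing
  (minima are π/R apart), and inclusive 55–84 nm size filtering.

The classic modelling interface is `hit_classifier()`, which returns a
`hit_ensemble` object with `print`, `summary`, `predict` and `plot`
methods. `run_pipeline()` chains every stage (simulate → train → predict →
size-filter → compare) from a single seeded configuration, and
`inst/cli/spihits.R` exposes the same stages as shell subcommands.

## A worked example

A CPU-scale run on the built-in toy detector (64×64, lower panel dead,
geometry preserving the real instrument's 0.130 m distance and 0.729 nm
wavelength):

```r
library(spihits)

g <- toy_geometry()
train_ds <- generate_dataset(sim_config(seed = 101), g, 100, 3900)
test_ds  <- generate_dataset(sim_config(seed = 202), g, 100, 1900)

ens <- hit_classifier(train_ds, model_config_small(),
                      train_config_small("maxf1", seed = 7))
summary(ens)
#> Cross-validation metrics (mean +/- sd over folds):
#>   f1        0.809 +/- 0.058
#>   precision 0.810 +/- 0.052
#>   recall    0.810 +/- 0.074
#>   predicted single hits: 100

preds <- predict(ens, test_ds)          # ensemble + mirror TTA
precision_recall_f1(confusion_counts(test_ds$labels, preds$label))
#> precision    recall        f1
#>    0.9681    0.9100    0.9381
```

(Numbers from a run with the seeds shown; the fit takes about 11 minutes on
one CPU core.) The per-fold metrics are reported as mean ± sd, and the
held-out F1 of the 20-vote ensemble (0.938) clearly exceeds the mean
single-model fold score (0.809) — the ensembling effect the method relies
on. On the synthetic stream the classifier must beat the chance-level F1 of
an all-positive classifier, 2p/(1+p) ≈ 0.095 at 5% prevalence; it does so
by a wide margin.

Downstream of classification:

```r
sel   <- predict(ens, test_ds, type = "selection", name = "cnn")
sizes <- vapply(sel$ids, function(id)
  estimate_size(test_ds$patterns[[match(id, preds$id)]], g)$diameter_nm,
  numeric(1))
size_filter(sel, sizes)                  # keep 55-84 nm diameters
psd_contrast(compute_psd(test_ds$patterns[test_ds$labels == 1], g,
                         normalize_frames = TRUE))
```

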