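# tbtfcnn

Two-class motor-imagery EEG decoding from the central electrodes C3, Cz
and C4, built around the lateralized suppression of the sensorimotor
rhythms: imagining a hand movement reduces mu-band (8–13 Hz) and
beta-band (17–30 Hz) power over the *contralateral* motor cortex
(event-related desynchronization, ERD). The package is aimed at BCI
researchers and students who want a complete, reproducible, single-CPU
implementation of a modern two-branch decoding pipeline together with
the classical baseline it is usually compared against.

What it provides:

* **Synthetic ERD/ERS simulator** (`simulate_dataset`) — 250 Hz,
  three-channel trials with narrowband mu/beta oscillations over 1/f
  noise and a configurable contralateral ERD depth, so every stage is
  runnable and testable without recorded data.
* **Preprocessing** (`prepare_network_inputs`) — 5th-order zero-phase
  Butterworth band-pass into the mu and beta bands, 0.5–4 s epoching
  (875 samples at 250 Hz), and stacking into `6 × 875` trial matrices
  (rows mu C3, Cz, C4, beta C3, Cz, C4).
* **Morlet time-frequency maps** (`cwt_morlet`, `trial_to_map`) — a
  continuous wavelet transform with
  `alpha = omega * fs / (2 * pi * f)` scale–frequency mapping,
  assembled into `64 × 93` maps (2 bands × 32 scales by 3 channels ×
  31 time bins, min-max scaled to `[0, 1]`).
* **Two-branch convolutional network** (`build_tbtf`, `run_cv`) — a
  temporal branch (conv `1×8` stride `1×8`, ELU) over the band-stacked
  signal and a time-frequency branch (conv `64×1`, ReLU) over the map,
  fused into a 2144-wide vector, classified by `dense(128, ReLU) →
  dropout(0.8) → dense(2, softmax)`; 278,466 trainable parameters.
  Training (Adam, lr 0.001, β₁ = 0.9, β₂ = 0.999, early stopping) and
  backpropagation are implemented in base-R matrix algebra and verified
  against finite differences. Single-branch ablations via
  `build_single_branch("eeg" | "cwt")`.
* **CSP-LDA baseline** (`run_csp_lda_cv`) — common spatial patterns
  from the generalized eigenproblem `Ra w = λ(Ra + Rb) w`, log-variance
  features, Fisher discriminant.
* **Evaluation** — stratified 10-fold cross-validation with per-fold
  and mean accuracy, Cohen's kappa `κ = (p0 − pe)/(1 − pe)` (pe = 0.5
  for the balanced two-class task), pooled confusion matrix and
  per-class precision/recall.

See `vignettes/motor-imagery-decoding.Rmd` for the model, the layout
conventions and every numerical choice.

## Worked example

```r
library(tbtfcnn)

cfg <- sim_config(n_trials_per_class = 30, erd_depth = 0.6,
                  noise_amplitude = 0.2, seed = 42)
trials <- simulate_dataset(cfg)
trials
#> <raw_trial_set> 60 trials x 3 channels x 1125 samples @ 250 Hz
#>   channels: C3, Cz, C4
#>   classes:  left=30, right=30

prep <- prepare_network_inputs(trials)   # filter, epoch, stack, CWT maps

report <- run_cv(build_tbtf(),
                 list(eeg = prep$eeg, cwt = prep$cwt, labels = prep$labels),
                 train_config(folds = 5, seed = 1))
report
#> <eval_report> tbtf: mean accuracy 1.000 (kappa 1.000) over 5 folds, n = 60
#>   per-fold: 1.00 1.00 1.00 1.00 1.00
#>   confusion (rows true, cols predicted):
#>        predicted
#> true    left right
#>   left    30     0
#>   right    0    30

baseline <- run_csp_lda_cv(prep$epochs, m = 1, folds = 5, seed = 1)
baseline
#> <eval_report> csp_lda: mean accuracy 1.000 (kappa 1.000) over 5 folds, n = 60
#>   per-fold: 1.00 1.00 1.00 1.00 1.00
```

At this ERD depth (0.6) and noise level the synthetic classes are
cleanly separable — a bandpower threshold on the C3 − C4 mu-power
difference already classifies essentially every trial — so both the
network and the baseline reach ceiling. The mean accuracy is the mean
of the per-fold accuracies (`p0`); the kappa printed next to it is
`2 * p0 − 1`. Harder regimes (shallower `erd_depth`, larger
`noise_amplitude`) separate the methods; label-shuffled controls fall
back to chance (accuracy ≈ 0.5, kappa ≈ 0).

A command-line wrapper is installed as `exec/midecode`
(`simulate`, `preprocess`, `cwt`, `train`, `baseline`, `summarize`).

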