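---
title: "Decoding motor-imagery EEG with a two-branch temporal/time-frequency CNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor-imagery EEG with a two-branch temporal/time-frequency CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbtfcnn)
```

## The decoding problem

Imagining a hand movement suppresses the power of the sensorimotor mu
(8--13 Hz) and beta (17--30 Hz) rhythms over the contralateral motor
cortex -- event-related desynchronization (ERD) -- and that lateralized
suppression is what lets a brain-computer interface tell an imagined
left-hand movement from a right-hand one using only the central
electrodes C3, Cz and C4. This package implements a complete two-class
decoding pipeline around that physiology:

1. **Preprocessing** -- channel selection, 5th-order Butterworth
   band-pass filtering into the mu and beta bands, extraction of the
   0.5--4 s post-cue epoch (875 samples at 250 Hz), and stacking of the
   two band-filtered signals into a `6 x 875` matrix per trial (rows:
   mu C3, Cz, C4, then beta C3, Cz, C4).
2. **Time-frequency representation** -- a Morlet continuous wavelet
   transform of each band-filtered row, assembled into a `64 x 93`
   nonnegative map per trial.
3. **A two-branch convolutional network** that fuses the temporal
   (band-stacked signal) and time-frequency (wavelet map)
   representations, plus its two single-branch ablations.
4. **A CSP-LDA baseline** -- common spatial patterns with log-variance
   features and Fisher's linear discriminant.
5. **Evaluation** -- stratified 10-fold cross-validation reporting
   per-fold and mean accuracy, Cohen's kappa, the pooled confusion
   matrix and per-class precision/recall.

A synthetic ERD/ERS simulator generates labeled trials with exactly the
structure the decoder assumes, so the entire pipeline is runnable and
testable without recorded data.

## The synthetic generator and what it does (not) emulate

`simulate_dataset()` produces 250 Hz, 4.5 s, three-channel trials. Each
channel is the sum of

* a mu-band and a beta-band oscillation -- each the sum of three
  sinusoids with per-trial random frequencies inside the band and random
  phases, scaled so each band carries power `rhythm_amplitude^2 / 2`.
  Narrowband sums of sinusoids (rather than filtered noise) were chosen
  because their band power is analytically checkable: attenuating the
  amplitude by `1 - erd_depth` attenuates band power by
  `(1 - erd_depth)^2` exactly, which the test suite verifies against an
  independent periodogram oracle (`band_power()`);
* 1/f-shaped (pink) background noise synthesized in the frequency
  domain and standardized to `noise_amplitude`, the standard first-order
  approximation of the EEG background spectrum.

During the imagery window (0.5--4 s by default, matching the analysis
epoch) the rhythm amplitude on the channel contralateral to the imagined
hand is multiplied by `1 - erd_depth`; an optional `ers_gain` raises the
ipsilateral amplitude (event-related synchronization is tied to rest and
movement termination, so it is off by default). Cz is never modulated.

The generator's default study conditions used throughout the package's
end-to-end evaluation are `erd_depth = 0.6`, `rhythm_amplitude = 1`,
`noise_amplitude = 0.2` and at least 100 trials per class: a
rhythm-dominant regime in which a simple bandpower threshold on the
C3 - C4 mu-power difference classifies over 90% of trials, so any
reasonable learned decoder has clear signal to find. No quantitative ERD
depth is established for real recordings; these values are conventions,
chosen once, that make the analytic oracle decisive.

What the simulator deliberately does **not** emulate: volume conduction
and realistic forward-model mixing between channels, eye-blink/EMG
artifacts, non-stationary drifts, inter-subject variability, and the
much lower single-trial SNR of real recordings. Passing the end-to-end
tests therefore demonstrates that the pipeline is implemented correctly
and can exploit lateralized band-power structure -- not that it attains
any particular accuracy on real data.

## Preprocessing choices

* **Filter realization.** The filters are 5th-order Butterworth IIR
  band-passes (a "Butterworth FIR" is a contradiction in terms;
  Butterworth designs are IIR). They are applied forward-backward
  (zero-phase) by default so band waveforms are not phase-shifted
  relative to each other; `filter_spec(..., zero_phase = FALSE)` gives
  the causal alternative. Filtering runs on the full 4.5 s trial before
  epoching, so edge transients fall outside the 0.5--4 s analysis
  window.
* **Epoch indexing** is 0-based and half-open with
  `sample = round(t * fs)`, which reproduces the canonical 875-sample
  trial exactly.
* **Artifact-flagged trials are kept by default** (the recording
  protocol this pipeline targets marks them with a "1023" event);
  `prepare_network_inputs(..., drop_artifacts = TRUE)` implements the
  exclusion alternative.
* **Normalization.** `normalize_epochs()` defaults to the conventional
  per-trial, per-row z-score (`scope = "row"`). The pipeline feeding
  the network's temporal branch, however, standardizes each trial
  globally (`scope = "trial"`). The reason is specific to ERD decoding:
  when the imagery window coincides with the analysis epoch, the class
  information in the temporal representation lives almost entirely in
  the *relative amplitudes* of the C3 and C4 rows. Row-wise z-scoring
  maps every row to unit variance and therefore erases exactly that
  contrast -- in the noiseless limit the two classes become identically
  distributed. Trial-global standardization removes overall scale (its
  purpose) while preserving between-row ratios. Both scopes are exposed
  and tested.

## The Morlet time-frequency map

The mother wavelet is `exp(i*omega*t) * exp(-t^2/2)` with `omega = 6`
(the standard choice respecting admissibility; smaller values distort
the frequency mapping). Scale `alpha` and translation `beta` enter as
`(1/sqrt(alpha)) * exp(i*omega*(t-beta)/alpha) * exp(-(t-beta)^2 /
(2*alpha^2))`, and the transform carries one further `1/sqrt(alpha)`
prefactor, so the overall envelope normalization is `1/alpha`. That
normalization makes a pure tone respond with the same peak magnitude at
every scale, so the map's argmax row tracks the tone frequency without
scale bias; the identification `alpha = omega * fs / (2*pi*f)` converts
between scale and physical frequency exactly. No conjugation is applied
to the wavelet inside the integral; for real signals this affects only
the phase of the coefficients, never the magnitudes the maps use.

The transform is computed by FFT cross-correlation with the wavelet
truncated at eight envelope standard deviations (tail mass ~1e-14); a
direct Riemann-sum implementation of the same integral serves as the
test oracle, and the two agree to near machine precision.

**Map assembly.** Nothing about the `64 x 93` map geometry is forced by
the architecture itself, so the package fixes a documented convention:
32 geometrically spaced scales per band (uniform relative bandwidth),
mu block above beta block (64 rows = 2 bands x 32 scales), and the
time axis of each channel mean-pooled into 31 contiguous near-equal
bins, concatenated C3 | Cz | C4 (93 columns = 3 channels x 31 bins).
With 875 samples the bins hold 28 or 29 samples each; for widths
divisible by the bin count, pooling conserves the grand mean exactly.
Each finished map is min-max scaled to `[0, 1]` (a map with zero spread
stays zero), which preserves the within-trial contrast between channel
blocks -- the lateralization the CWT branch learns from -- while
discarding absolute amplitude. Maps default to `|CWT|` magnitudes;
`cwt_config(power = TRUE)` switches to squared-energy maps.

## The network and its arithmetic

`build_tbtf()` declares the architecture; `propagate_shapes()` and
`count_parameters()` derive every feature-map size and parameter count
from it:

| stage | EEG branch | CWT branch |
|---|---|---|
| input | 1 x 875 x 6 | 64 x 93 x 1 |
| conv (32 filters) | 1x8, stride 1x8, same, ELU -> 1 x 110 x 32 (1568 params) | 64x1, stride 1x1, valid, ReLU -> 1 x 93 x 32 (2080 params) |
| max-pool 1x3, stride 1x3 | 1 x 36 x 32 | 1 x 31 x 32 |
| flatten | 1152 | 992 |

The fused 2144-wide vector feeds `dense(128, ReLU)` (274,560
parameters), dropout, and `dense(2, softmax)` (258 parameters) --
278,466 trainable parameters in total. The padding rules are the only
free choice and are pinned down by the printed shapes themselves: the
EEG convolution must be `same`-padded (875/8 -> 110) while the CWT
convolution and both pools are `valid`. Dropout is read as *drop
probability* 0.8 (the TensorFlow convention) and implemented as
inverted dropout. ELU uses `a = 1`. The single-branch ablations keep
their branch and the identical head; no extra fine-tuning is applied to
the EEG-only variant, a deliberate simplification that keeps the
ablation a pure branch removal.

Because no deep-learning framework is part of this package's
dependency set, `build_model()` realizes the network directly in matrix
algebra: both convolutions are exact patch-matrix products (the
temporal conv gathers 110 non-overlapping padded windows of 8 samples x
6 channels; the time-frequency conv takes each 64-high map column
whole), max-pooling and backpropagation are hand-derived, and
optimization is Adam (`beta1 = 0.9`, `beta2 = 0.999`, learning rate
0.001). The backward pass is verified against finite differences in the
test suite. Weight initialization is Glorot-uniform from a seeded
stream; all randomness (initialization, batch order, dropout, splits)
derives from one seed, so runs are bit-reproducible.

**Training settings** not fixed by the architecture: categorical
cross-entropy loss, batch size 32, at most 100 epochs with
patience-20 early stopping on a stratified 10% inner split of the
training folds (restoring the best-epoch weights). These are
conventional choices that keep a full 10-fold run on 200 trials around
three minutes on one CPU core.

## Evaluation

`kfold_split()` produces stratified folds (the conventional reading of
"divided into 10 equal subsets" that also prevents degenerate folds on
small synthetic sets); `run_cv()` trains a fresh model per fold and
aggregates. Accuracy is the mean of fold accuracies; Cohen's kappa is
`(p0 - pe)/(1 - pe)` with `pe = 0.5` for the balanced two-class task,
so `kappa = 2*p0 - 1`. One pass over the 10 folds is performed (not 10
repetitions of full cross-validation). The CSP baseline
(`run_csp_lda_cv()`) fits its filters inside each training fold only --
never on held-out trials -- and uses the same fold splits contract.

**CSP input representation.** The baseline consumes the same 6-row
band-stacked representation as the network's temporal branch, treating
the six band-channel rows as CSP channels (which also permits up to 3
filter pairs); with raw 3-channel input `2m <= 3` forces `m = 1`. The
band-stacked input is used *unstandardized*: CSP features are variance
ratios, and per-row standardization would erase them for the same
reason it erases the temporal branch's contrast. The generalized
eigenproblem `Ra w = lambda (Ra + Rb) w` is solved by whitening the
composite covariance; a ridge is added only if the composite is
numerically singular, keeping the eigenvalue-complementarity identity
(`lambda_a + lambda_b = 1`) exact in the regular case. Log-variance
ratios are floored at 1e-12 before the logarithm. The discriminant uses
the pooled maximum-likelihood within-class covariance, which makes the
fitted model invariant to duplicating the training sample.

## Numerical and degenerate-input conventions

* Zero-variance rows z-score to zeros; all-zero trials produce all-zero
  maps; a constant map min-max scales to zeros.
* Softmax subtracts the row maximum before exponentiation.
* Max-pooling breaks ties toward the earliest position,
  deterministically.
* Fold seeds, weight-init seeds and shuffle seeds are all derived from
  the user seed and kept inside 32-bit range.

## Problem sizes used in validation

The package's own end-to-end validation uses 100 trials per class at
the default study conditions for the headline comparison (two-branch
network, CSP-LDA baseline, and label-shuffled chance controls), 20
trials per class at near-zero noise for the perfect-separability check
of all three variants, and short 64--512-sample signals for the
wavelet-oracle comparisons. These sizes make the statistical targets
decisive (chance-level bands of +/-0.1, power-ratio tolerances of 20%)
while keeping a full run of the suite on one CPU core within minutes.

## Known limitations

* The synthetic generator's simplifications listed above mean measured
  accuracies do not transfer to real recordings.
* Reading the GDF files of the public motor-imagery benchmark is out of
  scope (no GDF reader is part of the dependency set);
  `read_recording()` implements the cue-epoching and artifact-flagging
  contract on a plain-text continuous-recording fixture instead, and
  `reported_bci2b_results()` carries the published reference accuracies
  for agreement checks only.
* The training engine implements exactly the declared architecture
  family (one conv-pool-flatten stage per branch, a two-layer head);
  it is not a general-purpose network library.
* Single-CPU training of the full two-branch model is minutes, not
  seconds; the CWT maps are the second-largest cost (a few seconds per
  hundred trials).
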