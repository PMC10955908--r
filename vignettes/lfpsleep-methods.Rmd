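---
title: "Sleep staging from subthalamic LFP: models, simulation and design choices"
author: "lfpsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging from subthalamic LFP: models, simulation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpsleep)
```

## The problem

Deep-brain-stimulation (DBS) electrodes implanted in the subthalamic nucleus
(STN) of Parkinson's disease patients can record local field potentials (LFP)
continuously, including during sleep. If 30-second epochs of STN LFP can be
classified into sleep stages (awake, NREM1, NREM2, NREM3, REM), an implanted
stimulator could adapt its therapy to the sleep state — a prospect of direct
clinical interest because sleep dysfunction is nearly universal in Parkinson's
disease and deep restorative sleep (NREM3) is particularly reduced.

`lfpsleep` implements that classification pipeline end to end: spectral
band-power features from multi-contact LFP, small and large feedforward
softmax classifiers trained with inverse-frequency-weighted cross-entropy,
exact Shapley attribution of each frequency band to each class probability,
and the evaluation grid (architecture x label scheme x sampling rate x
sub-band set, plus leave-one-subject-out validation). Because nocturnal
patient recordings of this kind are not publicly available, the package also
contains a first-class synthetic generator whose output exercises every stage
of the pipeline; all tests and the acceptance script run on it.

## The synthetic cohort generator

`sim_config()` describes a cohort: by default 10 subjects, 8-hour nocturnal
sessions, 4 DBS contacts sampled at 1024 Hz.

**Hypnograms.** Stage sequences are a 5-state Markov chain over 30-s epochs.
The default transition matrix is `s*I + (1-s) * 1 %o% pi` with persistence
`s = 0.92` (mean stage bouts of roughly 6 minutes) and target stationary
distribution `pi = (W .30, N1 .10, N2 .45, N3 .03, R .12)`. This rank-one
construction makes `pi` the exact stationary distribution, so prevalence is
controlled analytically; the scarce NREM3 mimics the Parkinsonian phenotype.
Sessions start awake, so short sessions over-express wake until the chain
mixes; tests that compare against the stationary distribution discard a
30-minute burn-in.

**Signals.** Each contact is the sum of

* a unit-RMS `1/f^slope` Gaussian background (default slope 1.5), synthesized
  in the frequency domain;
* one band-limited component per canonical band (delta 0-3, theta 3-7,
  alpha 7-13, low beta 13-20, high beta 20-30, low gamma 30-90, high gamma
  90-200, HFO 200-350 Hz), obtained by 4th-order Butterworth band-pass
  filtering of white noise. Filtering uses second-order sections designed
  from the analog prototype; the single-polynomial transfer function is
  numerically unstable for the narrow low-frequency bands at 1024 Hz and
  overflows on multi-hour signals, which is why the package carries its own
  SOS designer and a compiled biquad cascade;
* per-epoch amplitudes `10^((offset[stage, band] + jitter)/2)`, where
  `offset` is the stage profile matrix (log10 power units) and the jitter is
  i.i.d. `N(0, 0.1^2)` per epoch and band, shared across contacts. Epoch
  transitions are crossfaded over 0.5 s to avoid boundary clicks;
* a common-mode component injected identically on all four contacts at 20%
  of the mean contact RMS, so that bipolar referencing is consequential and
  testable.

The default stage profiles are *free parameters*, not measurements: they
plant a physiologically plausible and deliberately recoverable structure —
low-gamma (and secondarily high-gamma) elevation while awake, delta dominance
deepening through NREM2/NREM3 with suppressed beta and gamma, theta elevation
in NREM1, and a strong high-beta elevation in REM. Middle contacts carry
slightly stronger beta (gains 0.8/1.2/1.2/0.8), emulating the clinical
practice of selecting the bipolar pair with peak beta activity.

What the generator does **not** emulate: movement/cardiac artifacts, line
noise beyond the generic common mode, within-stage non-stationarity beyond
log-normal jitter, micro-arousals, inter-rater label noise, or any
patient-specific pathology beyond band-power structure. Consequently a
passing benchmark demonstrates that the pipeline recovers planted spectral
structure at realistic SNR and scale — not that it would reach the same
accuracy on patient recordings.

## Preprocessing

1. **Bipolar referencing**: `LFP01 = C0 - C1`, `LFP12`, `LFP23`. Common-mode
   signal cancels exactly (tests require >= 99% artifact power rejection).
2. **Channel selection**: the derivation with maximal mean 13-30 Hz Welch
   power over the session; ties and degenerate all-zero input resolve to the
   first channel.
3. **Optional downsampling** before everything else (125/250/400/700 Hz).
   Resampling is done by exact Fourier truncation rather than a polyphase
   FIR: the available polyphase implementation showed ~15% passband ripple
   and only -16 dB alias rejection at 1024→250 Hz, while spectral truncation
   is alias-free by construction (a 200 Hz tone leaves < -40 dB residual and
   a 10 Hz tone is preserved within 1%). The band scheme is then truncated
   at the new Nyquist: at 250 Hz seven bands remain and high gamma becomes
   90-125 Hz.
4. **Spectrogram**: 2-s Hamming windows sliding by 1 s give 0.5 Hz bins; the
   15 window-PSDs whose start falls in each 15-s frame are averaged (the
   aggregation into frames is a package choice; only the two resolutions are
   externally fixed). Scaling is one-sided density, so the PSD integrates to
   the signal variance (checked to 5% on white noise).
5. **Band powers**: per 30-s epoch (two frames), the mean of the PSD bins
   with `f_low <= f < f_high`. Band edges are half-open so touching bands
   partition the axis; the DC bin is excluded from delta because DC offset
   is referencing-dependent, not physiological. Epochs with incomplete
   frames (the recording tail) are dropped, not padded.
6. **Normalization**: per subject and band, subtract the mean and divide by
   the standard deviation. The external contract says "scaling by the
   variance", which is ambiguous; the conventional z-score reading is the
   default and a `scale = "var"` switch provides the literal reading.
   Statistics are computed on the training split only and reused on held-out
   epochs of the same subject (a `normalization = "full"` switch reproduces
   the leakage-prone variant). A caveat discovered in testing: with short
   sessions, per-subject statistics depend on the subject's stage
   composition, which can shift feature baselines between subjects; this is
   inherent to per-subject scaling, and it is why cross-subject experiments
   in the test suite use faster-mixing hypnograms.

The normalized features are invariant to a global gain of the raw voltages
(both the mean and the SD scale by `c^2`), verified to 1e-6.

## Classifiers

`stagenet()` fits a fully connected softmax network by plain minibatch SGD on
the weighted categorical cross-entropy, with two built-in capacities:

| | original | large |
|---|---|---|
| hidden layers | 32 | 1000, 1000 |
| batchnorm / dropout | none | yes / 0.5 |
| learning rate | 1 (fixed) | 0.1, halved every 100 epochs |
| training epochs | 100 | 1000 |

Design points the external description leaves open, fixed here: batch size
256; He-uniform initialization; layer order linear → batchnorm → ReLU →
dropout; class weights `w_c = N/(K*N_c)` normalized so balanced data gives
unit weights; no early stopping (the long schedule deliberately trains past
interpolation, leaning on double descent). Label schemes: `three_state`
(awake / NREM / REM) and `four_state` (awake / NREM1 / NREM2&3 / REM —
NREM3 is too scarce in this population to stand alone). The 75/25 split is
stratified by stage within subject by default (`stratify = FALSE` gives the
purely random variant); temporally adjacent epochs may straddle the split,
which is optimistic relative to a session-blocked split and is the reason
leave-one-subject-out numbers are always reported alongside.

Training is bit-reproducible given a seed: initialization, shuffling and
dropout masks all draw from R's RNG inside the compiled loop.

## Exact Shapley attribution

For each epoch, band and output state, the attribution is the exact Shapley
value over all `2^n` band coalitions (guarded at n <= 15). The coalition
value of a subset S is the *interventional expectation*: features in S keep
the epoch's values, the rest are substituted from a background sample
(default: seeded draw from the training split) and the model outputs are
averaged. With the empty set this reduces to the background-mean prediction,
i.e. roughly the class prevalences for a calibrated model; with the full set
it is exactly the model prediction, and the enumeration then guarantees
efficiency (contributions + base = prediction) to numerical precision. A
single-row background gives the cheaper mean-imputation variant. Attribution
is on softmax probabilities, not logits. Summaries report the median |SHAP|
per true state and band; the permutation-form average over all feature
orderings serves as an independent oracle in the tests (agreement to 1e-10).

## Evaluation

`confusion_summary()` reports the predicted x true table and one-vs-rest
accuracy, sensitivity (= recall), specificity, precision and F1 per class —
the one-vs-rest reading is the only one under which per-class "accuracy" is
well defined. Classes absent from the truth get `NA`, never 0.
`per_subject_error()` reports the across-subject mean and, by default, the
*population* SD (the convention the worked examples imply), with
`sd_type = "sample"` available; the convention is recorded in the output.
Leave-one-subject-out normalizes the held-out subject with its own
statistics by default (per-subject scaling is part of the feature contract;
a `pooled` mode applies averaged training-subject statistics instead).

## Benchmark problem sizes

The package's planted-effect benchmark — used by the acceptance tests and
`scripts/acceptance.R` — runs 10 subjects x 1 h at 1024 Hz (≈ 1190 usable
epochs), trains the large network for 200 epochs (its loss is flat over the
last quarter of training at this data size; the canonical 1000-epoch
schedule adds nothing but time here), the original network at its canonical
100, attributes 100 held-out epochs against a 50-epoch background, and runs
the sub-band ablation (all bands vs high beta, low gamma, and both) over 3
seeds at 100 training epochs per cell. These sizes are the package's choice
of a desk-scale experiment; the generator's defaults remain the full-night
conditions (8 h sessions).

## Known limitations

* The synthetic benchmark shares its band vocabulary with the classifier;
  real LFP violates the generator's independence and stationarity
  assumptions, and no claim about patient-data accuracy follows from it.
* Per-subject normalization entangles stage composition with feature
  location (see above); cross-subject transfer degrades when compositions
  diverge — visible in the heterogeneous leave-one-subject-out test.
* The EDF writer covers the continuous 16-bit single-rate case only (no
  EDF+ annotations); physical ranges are symmetric two-significant-digit
  bounds, so stored voltages quantize to `range/65535`.
* Exact enumeration is exponential in the number of features; beyond 15
  features a sampling approximation would be required, which this package
  deliberately does not implement.
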