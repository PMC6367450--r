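---
title: "Decoding single M/EEG trials with spatial-summary convolutional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding single M/EEG trials with spatial-summary convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megnet)
```

## The problem

A single trial of magnetoencephalography or electroencephalography is a
short multichannel time series — here a tensor of `T` samples by `C`
channels — time-locked to a cue. Classical decoding pipelines mix the
channels into components (PCA/ICA/CSP), apply a filter bank to each
component, summarize the filtered components into features, and classify
the features. `megnet` implements a family of neural networks that fold
this pipeline into a single end-to-end trainable model, together with
the evaluation protocol (subject-wise cross-validation against held-out
subjects), a cropped-trial augmentation scheme, an interpretation suite,
and a synthetic-data generator that makes every stage testable without
any recording.

## The SCNN model

The **spatial-summary convolutional network** factorizes the first
stages of the pipeline:

1. *Spatial summary.* A stack of convolutions act only across the
   channel axis, identically at every time point. A layer whose kernels
   have `taps` coefficients maps `P` channel positions to `P - taps + 1`;
   the stack must collapse the axis to exactly one position, leaving `S`
   learned non-linear channel mixtures ("spatial components") per time
   point. Convolutions are "valid" (no padding) and bias-free; every
   activation (ReLU, ELU or SELU) is followed by batch normalization,
   which makes biases redundant.
2. *Temporal filtering.* `F` one-dimensional convolutions along time act
   as a learned filter bank over the spatial components, optionally
   followed by non-overlapping average pooling (a low-pass and
   parameter-reduction step, not a learned one).
3. *Classification head.* The pooled feature maps are flattened and fed
   through fully connected layers to class logits.

`plan_shapes()` walks this arithmetic for a configuration and input
geometry, rejects spatial stacks that do not collapse the channel axis,
and reports the exact trainable-parameter count; the test suite holds it
to the shapes and counts the built model actually realizes.

The **Ra-SCNN** keeps stages 1–2 as a front end (trained jointly, never
frozen) and replaces the head with an LSTM whose input at every step is
a *soft-attention* weighted summary of the entire feature sequence: a
small feed-forward network scores every sequence position given that
position's feature vector and the previous LSTM state; scores are
softmax-normalized per feature across positions, and the weighted sum
forms the step input. The classifier reads either the full output
sequence or the final state.

Because this R stack has no deep-learning backend, the entire engine —
forward passes, backpropagation (including backpropagation through time
across the attention and LSTM), Adam, batch-norm statistics, dropout —
is implemented in the package on top of BLAS matrix products. Every
layer's analytic gradient is checked against central differences in the
test suite, which is the strongest correctness guarantee this kind of
code can carry.

## Training protocol

Evaluation is **subject-wise**: a set of test subjects is excluded from
all folds, and each remaining subject's trials land in exactly one fold
(`assign_folds()` orders subjects by trial count and assigns each to the
currently lightest fold, giving near-equal fold totals; ties are
deterministic). Leakage of a subject across train/validation/test is
impossible by construction and asserted in the tests.

Losses support two refinements from the protocol the package
implements:

* *Class-imbalance weights*, `1 - n_class/n_total` per class, multiply
  each example's loss by the weight of its true class.
* *Ordinal label smoothing* for ordered targets: the true class receives
  0.6 with 0.2 on each immediate neighbour (0.8/0.2 at the two boundary
  classes). `one_off_accuracy()` is the matching metric: the fraction of
  predictions within one class of the truth.

`transfer_evaluate()` measures feature carry-over: all network weights
are frozen, the classification layer is discarded, and a linear
max-margin head (SVM) is trained on the penultimate features of new-task
training subjects and scored on held-out subjects.

`hyper_search()` is a seeded random-search driver over named dimensions
(uniform, log-uniform, integer, choice) with a persistent trial log; the
sampler is pluggable so model-based optimizers can be slotted in where
available.

## Cropped-trial augmentation

`crop_augment()` slides a fixed-length window over each trial and emits
every placement (optionally only those containing the event onset,
under the half-open convention `s <= event < s + W`) as a new training
trial. At stride 1 the number of start offsets for a trial of duration
`d` seconds is `(d - window) * rate` — offsets `0 .. (d-window)*rate - 1`
— which for 3.5 s trials, a 2 s window and 200 Hz gives the 300:1
augmentation the architecture diagram's `T = 400` input geometry
corresponds to. Crops are exact contiguous slices; event indices are
re-expressed relative to each crop. The preprocessing order is fixed:
resample → band-pass → epoch → (optional) crop.

Two preprocessing notes: resampling is implemented as zero-stuffing plus
a zero-phase Butterworth anti-aliasing filter and decimation with
reflection-padded edges (exactly unit DC gain; in-band sinusoid
amplitudes preserved within 5%), and the band-pass filter is zero-phase
(forward–backward), so no group delay ever shifts an event index. When
the upper band edge reaches the Nyquist frequency the band-pass
degenerates to a high-pass at the lower edge.

## The synthetic generator

`generate_trialset()` emulates the statistical structure the method
assumes, not sensor physics:

* a zero-mean background with power spectral density proportional to
  `1/f^exponent`, synthesized in the frequency domain (deterministic
  amplitudes, uniform random phases) and standardized per channel —
  the test suite checks the realized log-periodogram slope;
* class-dependent band-limited oscillations on a channel subset, with a
  per-trial frequency drawn inside the band and random phase. An effect
  of amplitude `m` is calibrated so affected channels carry `m` times
  the background band power (`m = 1` is exactly "no effect", the knob
  used for chance-level controls);
* per-subject channel-gain jitter (±10% by default), so that unseen
  subjects are genuinely harder than unseen trials of seen subjects;
* event-free baseline recordings per subject and task.

The default spectral exponent is 1.0 — a choice, since encephalographic
background is only characterized here by its 1/f prior. What the
generator does **not** emulate: volume conduction and realistic sensor
covariance, artifacts (blinks, cardiac), non-stationarities, or any
anatomy. Passing tests on this generator demonstrate that the
implementation recovers planted structure under the model's
assumptions; they say nothing about decoding accuracy on real
recordings.

## Validation experiment

The package's reference experiment trains the SCNN on a generated
dataset of 24 subjects × 40 trials (32 channels, 200 Hz, 2 s trials,
event at 0.5 s): class A carries an 8–12 Hz effect and class B an
18–22 Hz effect, each doubling band power on eight channels. Four
subjects are held out entirely; the rest form five subject-wise folds.
The architecture used is deliberately small — one spatial collapse
layer with 6 kernels, 12 temporal filters of 33 taps, average pooling
of width 40, ReLU, no hidden dense layer, L2 `1e-4` — trained with Adam
(learning rate `1.5e-3`, batch 64, 22 epochs). Mean held-out-subject
accuracy reaches ~0.99, and the whole five-fold run takes a few minutes
on one CPU; these problem sizes are the package's validation choices,
chosen to exercise the full protocol at desk scale.

Two lessons from developing this experiment are worth recording. An
over-parameterized head (a wide dense layer on hundreds of pooled
features) memorizes training subjects while staying at chance on unseen
subjects — the subject-wise protocol is exactly what exposes this.
And frequency selectivity needs room: short temporal kernels with weak
capacity failed to separate 10 Hz from 20 Hz structure.

## Interpretation suite

**Activation maximization.** `maximize_activation()` performs
regularized gradient ascent on `f_o(x) - theta * sum(x^2)`, normalizing
the gradient by its RMS at every step, stopping after `patience` steps
without improvement (improvement below `1e-8` counts as none) or at the
iteration cap; defaults are `eta = 0.2`, `theta = 0.05`, 10000
iterations, patience 5, and a zero-mean 1/f initialization. The
returned input is the best iterate. Two model objectives are exposed:
a spatial component's summed output with respect to the model input
(for topographies), and a class score with respect to the
spatial-stage sequence (for spectro-temporal signatures). The class
objective maximizes the *logit* (by default the logit contrast against
the other classes): a softmax probability saturates at 1, kills the
gradient, and stalls the ascent.

Numerical choices that matter here: on the validation experiment's
models the logits are orders of magnitude steeper than in the paper's
setting, so the analysis uses `eta = 0.05`, `theta = 0.005`,
patience 10; and the interrogated model is selected by the protocol's
own rule — the fold with the highest held-out test accuracy, ties to
the lowest fold index. On that model the generated activations'
dominant spectral bins land inside the injected 8–12 Hz and 18–22 Hz
bands. A caveat the package reports honestly: for some fold models the
class-B objective is globally maximized by large low-frequency input —
a preference that only exists far off the data manifold (the class-B
effect has the lower absolute power, since the 1/f background is weaker
in its band). For such cases `spectral_lambda` adds a penalty on
deviation of the generated input's amplitude spectrum from the 1/f
template (analytic FFT-domain gradient), keeping the ascent on the
manifold at the cost of making the raw dominant-bin readout reflect the
prior rather than the class.

**Topographies and spectrograms.** `topography_map()` interpolates
per-channel weights over a planar layout (local three-nearest-channel
planar interpolation, inverse-distance fallback for degenerate
neighbourhoods; exact at the channels themselves). No anatomical claims
are made — maps live in channel space on whatever 2-D layout is
supplied. `activation_spectrogram()` computes Hann-tapered short-time
power spectral density in dB (64 FFT bins, 50-sample overlap; the
window length, unstated in the protocol, defaults to 64 samples and is
configurable).

**Obscuring profiles.** `obscure_trial()` replaces a growing portion of
a trial by a 1:1000 signal:noise convex mixture `(x + 1000*n)/1001`
(the unnormalized reading would explode amplitudes), with uniform noise
scaled to each channel's standard deviation. Growth is geometric: the
post:pre ratio matches the trial's own event geometry (6:1 for an event
at 0.5 s of 3.5 s), growing outward from the event or inward from both
ends. `obscuring_profile()` tracks the softmax probability of the
correct class — probabilities, unlike logits, are comparable across
trials — for each subject's highest-confidence correctly classified
trial per task, over 10 noise draws per step, and
`fit_profile_slope()` fits the declining segment. `baseline_control()`
implements the two control conditions: classifying event-free baseline
segments alone, and classifying accurate trials minus the subject's
across-task mean baseline. The tests drive both with an oracle model
sensitive only to a known event-locked window, for which the expected
profile (flat until the window is touched, then declining) and control
outcomes (chance vs above-chance) are known by construction.

## Comparison features

The feature pipeline mirrors the classical baseline: 50 ms rectangular
windows with 25 ms overlap (79 windows on a 2 s epoch), per-window
means (plain, absolute, quadratic, and non-zero-only variants),
variance, skewness, kurtosis, RMS, log energy, short-FFT magnitudes
(8-point for 200 Hz channels, realized by truncation; zero-padding is
configurable), LPC coefficients (autocorrelation method, order 4 by
default), and the circular autocorrelation computed as
`iFFT(|FFT(w)|^2)` — held to a brute-force quadratic-time oracle at
`1e-10`. Channel mixing into components is a pluggable matrix (identity
by default); independent-component estimation itself is out of scope.
`select_features()` keeps columns passing both a Bonferroni-corrected
Pearson p-value threshold and an absolute-correlation floor; constant
columns are excluded with a warning. Skewness and kurtosis of a
constant window are reported as 0 with a warning rather than NaN.

## Degenerate inputs and numerical conventions

All sample indices are 0-based offsets from trial start; `event_index`
may be `NA` (baselines). Cropping with window = trial length yields the
single identity crop. A window that can never contain a required event
is an error naming the trial; a cue too close to a recording edge is a
skipped warning, not an error. Softmax and attention normalizations use
max-subtraction; the cross-entropy clamps probabilities at `1e-12`;
zero-gradient ascent steps leave the input unchanged rather than
dividing by a zero RMS. Batch normalization uses momentum 0.1 and
`eps = 1e-5`, with running statistics making evaluation-mode forward
passes exactly deterministic. Every stochastic operation (generation,
initialization, shuffling, dropout, noise draws, search) flows from an
explicit seed and restores the caller's RNG state.

## Known limitations

* The generator's realism limits are listed above; headline accuracies
  on real MEG/EEG are not reproducible here and are not claimed.
* Activation maximization inherits the usual fragility of input
  optimization: local optima and off-manifold preferences (see above);
  multiple restarts and the spectral prior are provided, not silver
  bullets.
* The hyperparameter driver ships only with random search; the search
  spaces used in any given study are experiment choices, not package
  defaults.
* Vendor formats (FIF/CTF/EDF/GDF) are not parsed; data enter through
  the documented array container or the `trial_set()` constructor.
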