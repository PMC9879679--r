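---
title: "Abstracted emotional EEG topographic maps with stacked autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abstracted emotional EEG topographic maps with stacked autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative EEG renders one scalar per electrode as an interpolated scalp
image.  Classically that scalar is a single feature -- an alpha band power,
an entropy -- so a ten-feature analysis produces ten maps per condition.
`saetm` implements an alternative: per channel, a stacked autoencoder (SAE)
compresses ten linear and nonlinear features of every 2-s analysis window
into one abstracted scalar, supervised so that the compression is
informative about binary valence or arousal.  The 32 channel scalars form a
single topographic map whose class distinctiveness can be quantified by a
small convolutional image classifier.

The pipeline is: preprocess a 32-channel recording (10-20 montage, 128 Hz),
window the trial, compute ten features per window and channel, normalize to
the pre-stimulus baseline, pretrain one three-layer SAE per channel with a
correlation-based structural loss choosing each hidden width, fine-tune all
parameters against valence or arousal labels through one-neuron channel
heads and a two-neuron output, and interpolate the 32 head outputs over the
scalp.

## Features and their parameters

Each 2-s window (256 samples, 50% overlap; a 60-s trial yields 59 complete
windows) of each channel yields, in fixed order: mean Welch power spectral
density over theta (4-8 Hz), alpha (8-12), beta (12-30) and gamma (30-45);
mean; sample standard deviation (N-1); zero-crossing rate with `sgn(0) = 0`;
Higuchi fractal dimension; approximate entropy; correlation dimension.

* **Welch PSD**: Hann window, 128-sample segments, 50% segment overlap.
  Band power is the *mean* density over bins `lo <= f < hi`, i.e. an
  average PSD rather than integrated power; for flat spectra it equals
  `variance / (fs/2)`.
* **Higuchi fractal dimension** (`kmax = 10`): the curve-length estimator
  standard in EEG work.  The generic box-count relation `N = eps^-D`
  admits many estimators; Higuchi's is the one used on sampled series.
  A constant window returns 1.
* **Approximate entropy** (`m = 2`, `r = 0.2 sd`): Chebyshev distance,
  self-matches included, `ApEn = phi^m - phi^(m+1)`.  A zero-variance
  window returns 0.
* **Correlation dimension** (embedding dimension 5, delay 1): pair counts
  `C(eps)` over a 10-point log-spaced grid spanning the 5th-50th
  percentile of pairwise embedded distances; the estimate is the
  least-squares slope of `log C` against `log eps`, floored at 0.

Features are min-max normalized per channel and feature against the extrema
over the baseline windows, `v' = clip((v - min_b)/(max_b - min_b + 1e-12),
0, 1)`, so "1" means "at or above the largest baseline value".  The three
nonlinear estimators are implemented in C++ for speed and are checked in
the test suite against independent literal O(N^2) R implementations.

## Preprocessing

`preprocess()` applies a zero-phase 4th-order Butterworth band-pass
(0.05-47 Hz) and polyphase resampling to 128 Hz.  The forward-backward pass
is realized *spectrally*: the squared analog band-pass magnitude is applied
in the frequency domain.  A recursive realization is numerically unstable
at a 0.05 Hz edge (the normalized cutoff is ~4e-4), and its state
transients ring for tens of seconds, so the spectral form -- the
infinite-length limit of forward-backward filtering, with periodic boundary
-- is both more exact and free of group delay that would shift window
boundaries.  The cost is periodic wrap-around at the recording edges;
windows near the very edges of short recordings should be interpreted
accordingly.  Filtering this way is idempotent to ~1e-7 for content in the
flat pass band; content on the filter shoulders (above roughly 8 Hz the
4th-order band-pass deviates from unit gain by more than 1e-6) is slightly
re-attenuated by a second pass, as with any finite-order filter.

## The synthetic corpus

DEAP, the study corpus this package is designed around, is licensed and
cannot ship here; `synthdata` generates a corpus with the same shape: 32
channels at 128 Hz, 60-s trials after a 5-s baseline, 40 trials per
participant split 8/10/10/12 over the HAHV/LAHV/HALV/LALV quadrants, and a
random +/-20% per-participant gain.  Each channel is `1/f^beta` Gaussian
background (default `beta = 1`, RMS 10 uV, classic EEG slope) plus
band-limited oscillations: alpha (RMS 4 uV) on the ten frontal channels and
beta+gamma (RMS 2 uV each) on the nine posterior channels.

Class structure is planted as *multiplicative amplitude scalings during the
trial segment only* (so baseline normalization stays meaningful): high
valence scales left-frontal alpha (Fp1, AF3, F3, F7, FC5) by
`valence_effect`, low valence the right homologs -- the hemispheric valence
hypothesis, giving map checks a known lateralized ground truth -- and high
arousal scales posterior beta+gamma by `arousal_effect`.  The default
effect ratio 1.5 is a moderate, physiologically plausible asymmetry; the
learnability and map experiments in the tests and the acceptance script use
ratio 3 with 200 training and 60 held-out trials, a deliberately strong
planted effect standing in for the (unavailable) real effect.  What passing
these experiments shows is that the pipeline *transmits* planted class
structure end to end -- features, compression, supervision, maps; it does
not show that real EEG carries its emotion signal this strongly, and
accuracies here should not be read as forecasts of DEAP accuracies.
Artifacts (EOG/EMG), inter-channel correlation, volume conduction and
nonstationarity are not emulated.

## The per-channel stacked autoencoder

Each autoencoder layer is tied-weight: `h = sigmoid(x W + b)`,
`x' = sigmoid(h W^T + c)`, trained by plain mini-batch SGD on the summed
squared reconstruction error.  Stacks have exactly three hidden layers.
Hidden widths are chosen per layer by the structural loss function

    SLF = 0.5 (1 - rho_Pearson)^2 + 0.5 (1 - rho_Spearman)^2

between the flattened input matrix and its reconstruction: one candidate
autoencoder is trained per width `1..w` (where `w` is the current input
width) and the smallest width within `slf_tol = 1e-3` of the minimum SLF
wins.  Two numerical choices deserve explanation:

* **Tie tolerance.**  On trainable data the SLF decreases monotonically
  with capacity, so a strict argmin always selects the largest width; the
  knee of the curve is the object of interest.  Treating SLF differences
  below 1e-3 (on the [0, 4] SLF scale) as ties recovers the knee: on
  sigmoid(rank-k factor) matrices with k in {2, 3, 5} the chosen width
  falls within +/-1 of k in 10/10 seeded runs.
* **Learning rate.**  Pretraining uses lr 0.5, batch 32, 200 epochs by
  default.  At much smaller rates the tied sigmoid autoencoders underfit
  within any practical epoch budget and the SLF knee is blurred away.

Pretraining can subsample the pooled feature rows (`max_rows`): successive
windows overlap by 50% and are highly redundant, so this bounds runtime
without changing what is learned.

Fine-tuning attaches a one-neuron sigmoid head per channel
(`U_i = sigmoid(mu . h + bias)`) and a two-neuron sigmoid output over the
32 head outputs, and backpropagates cross-entropy against one-hot targets
(low = (1,0), high = (0,1)) through *all* parameters -- encoders, heads,
output.  Updating only the output layer would leave the map values
condition-independent and could not produce distinct per-quadrant maps;
supervision must reach the heads.  One binary model is trained per emotion
dimension; quadrant predictions are the conjunction.  Pretraining is
label-free, so one pretrained stack seeds both models.  Trial-level
predictions average the window-level outputs.

## Topographic maps

The map scalar of channel i starts from the mean of `U_i` over the trial's
windows and is, by default, *referenced to the pre-stimulus baseline*:
`clip(0.5 + mean(U_trial) - mean(U_baseline), 0, 1)`, where the baseline
windows pass through the identical feature extraction, normalization and
network.  Each sigmoid head has an arbitrary operating point at neutral
input, so raw head means confound activation with initialization; the
baseline-referenced value reads as event-related change -- 0.5 means "no
change from rest" on every channel -- which is how classical QEEG maps are
interpreted.  On a no-effect synthetic corpus the mean left-right frontal
contrast drops from ~0.16 (raw, pure initialization offset) to ~2e-4
(referenced), while the planted high-valence frontal asymmetry stands at
~0.24.  `interpolate_topo()` realizes "bilinear" interpolation in its
scattered-data form: piecewise-linear interpolation over the Delaunay
triangulation of the 32 idealized 10-20 electrode positions
(azimuthal-equidistant projection, nose +y, outer ring at radius 0.8,
Cz at the origin; right-hemisphere sites are exact mirrors of the left).
Grid nodes inside the head disc but outside the electrode hull take the
nearest electrode's value, with ties averaged.  Because several electrode
quadrilaterals are nearly cocircular, the Delaunay diagonal choice is
ambiguous there; the interpolant is averaged with its own mirror image,
which restores exact left-right symmetry while preserving electrode
exactness and linear precision.  Maps render to PNG through a fixed
blue-to-red colormap over a declared `value_range` (default (0, 1), the
range of normalized features and sigmoid outputs) so that map sets share a
scale.

For the four-quadrant map-classification experiment each trial's SAETM map
averages the channel values of the valence and the arousal model: each
binary model organizes one planted contrast, and their mean carries both,
which is what a single per-trial map must do.

## Scoring map distinctiveness

`train_map_cnn()` trains a small CNN -- conv 3x3 (8 filters, stride 1),
max-pool 2x2 (stride 2), conv 3x3 (16), pool, dense 32, softmax -- with
sigmoid activations and RMSprop (lr 0.001, decay 0.9) on down-sampled map
*grids*, never on rendered PNG pixels, which would confound the comparison
with the colormap.  The default configuration (10 epochs, 64x64 input)
matches the classifier as stated; the package's own comparison experiments
pass `epochs = 60, input_res = 32` instead, because the optimization
budget, not the epoch count, is what transfers across corpus sizes: with
~60 maps and mini-batches of 2 (batch size is otherwise unstated), 10
epochs are ~200 RMSprop updates -- far too few at lr 0.001 to leave the
initialization, where the corpus the configuration was written for
provides orders of magnitude more -- and a 32x32 grid loses nothing when
the map has only 32 electrode degrees of freedom.  Splits are stratified;
`split = "holdout"` uses one stratified quarter as the test set,
`split = "kfold"` the full k-fold protocol (k = 10 by default, each fold
0.1 of the data).  `compare_map_methods()` runs the classifier on the ten
single-feature map sets and the SAETM set and tabulates mean +/- sd
accuracy -- 11 rows.

## Problem sizes and runtime choices

The package's own experiments (tests, acceptance script) use: 200 training
trials (5 synthetic participants), 60 held-out trials, effect ratio 3;
pretraining with 40 epochs, `max_rows` 1000-2000; fine-tuning for 20
epochs; every experiment tensor is extracted at `window_step = 2`
(non-overlapping 2-s windows -- consecutive 50%-overlap windows share half
their samples, so this halves extraction cost at negligible information
loss);
map classification on 32x32 grids (60 epochs) with a stratified holdout.  These sizes
keep the full pipeline in the tens of minutes on one CPU while leaving all
planted-effect checks comfortably clear of their thresholds.  The
structural-loss width search re-trains one autoencoder per candidate width
per layer per channel, and is the dominant pretraining cost.

## Known limitations

* The synthetic generator omits artifacts, inter-channel correlation and
  volume conduction; ICA cleaning of real recordings is out of scope
  (recordings are assumed artifact-free on input).
* The spectral zero-phase filter treats recordings as periodic; very short
  recordings see wrap-around at their edges.
* EDF support is a minimal 16-bit subset (one data record, physical range
  pinned to the digital range) sufficient for round-tripping
  integer-microvolt data, not a general EDF(+) implementation.
* The CNN instrument measures *separability of map sets*, not emotional
  content per se; a feature that leaks any class-correlated signal into
  maps will score above chance.
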