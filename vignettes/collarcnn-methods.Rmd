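---
title: "Classifying cattle behaviour from collar accelerometers: models, pruning and deployment accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cattle behaviour from collar accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collarcnn)
```

## The problem

Neck-mounted collars with 3-axis accelerometers are the workhorse of
precision livestock monitoring: rumination and eating time are leading
indicators of health and oestrus in cattle, and collars can observe them
continuously where human scoring cannot. `collarcnn` implements a complete
pipeline that turns raw 10 Hz collar streams into per-window behaviour
classifications — `RUMINATION`, `EATING`, `OTHER` — with a compact 1D
convolutional network, and then shrinks that network, by structured filter
pruning and half-precision storage, until it fits the SRAM and energy
budget of the micro-controller inside the collar.

Ground-truth labels in this setting come from muzzle-mounted pressure
halters that score jaw activity directly. The package treats halter labels
as given, merges them onto collar samples by timestamp (nearest neighbour
within ±0.05 s, half the sampling interval, because the two devices run
independent real-time clocks), and never models halter internals.

## Signal model and preprocessing

A collar shifts and rotates on the neck, so each axis carries a slowly
drifting gravity projection on top of the motion signal. The pipeline
removes it with a first-order difference per axis,
$\Delta s[t] = s[t] - s[t-1]$, which cancels any locally constant offset
exactly while preserving the oscillatory chewing signature. Differencing
is applied to the full trace *before* windowing, so every window has
exactly $L = \text{window\_seconds} \times 10$ samples; per-window
differencing would have produced $L-1$ samples and changed the geometry.

Windows are contiguous and non-overlapping (90 s by default; 60 s and
120 s supported for the window-length study), the trailing remainder of a
trace is dropped, and each window takes the majority-vote label of its
samples. Ties are broken by the fixed declaration order
`RUMINATION > EATING > OTHER` — an arbitrary but deterministic rule, made
explicit because the label vote is part of the data contract.

Because animals spend very different amounts of time in each state, the
window set is balanced by random undersampling so that every animal
contributes the same number of windows per class (the common count is the
minimum over all animal-class cells). Balancing by undersampling rather
than augmentation keeps every retained window a genuine observation.

## The classifier

The network is deliberately small: three convolutional blocks
(64 filters, kernel 16, stride 2 by default) on the 3 input axes, a
kernel-1 "expansion" convolution that widens the feature map to 512
channels, adaptive average pooling over time, and a fully connected
512→3 head. Every convolution is followed by dropout (p = 0.25),
batch-normalisation and ReLU, in that order. Adaptive pooling is what
lets one trained model classify 60 s, 90 s and 120 s windows alike.

The stride of the kernel-16 blocks is configurable; operation counts are
stride-dependent, so every MACC figure the package reports is stamped
with the input length and settings it was computed under.

Training uses AdamW (base learning rate $10^{-4}$, decoupled weight decay
$\lambda = 0.01$), batch size 256, and a one-cycle learning-rate policy:
cosine warm-up from the base rate to $10\times$ base over the first 30 %
of steps, then cosine annealing to base/100. Only the policy shape is
standardised; the peak multiple and warm-up fraction are package choices,
exposed in `train_config()`.
Early stopping monitors validation loss with patience 15 and minimum
improvement 0.01, and the returned model is the best-validation-loss
state, not the last one.

Cross-validation is grouped by animal: unique animal ids are shuffled and
sliced into 5 contiguous folds, so windows from one animal never appear
on both sides of a split. This is the single most important protocol
choice in the pipeline — per-window splits leak animal identity and
inflate scores — and the leakage guard is asserted in code, not just in
tests.

## Structured pruning

Filter importance is the $\ell_1$ norm of the filter's weights (bias
excluded). Pruning is structured: a removed filter takes with it its
bias, its batch-norm scale/shift, and the matching input-channel slices
of the next layer (or head columns after the expansion block), so the
reduced model is genuinely smaller in memory and compute. Surviving
weights are carried over bit-exactly.

Each pruning stage removes a fraction $s_f = 0.5$ of the stage-initial
filters of every block, spread over $n = 35$ iterations at every epoch
($\Delta t = 1$) according to the cubic schedule

$$ s_t = s_f - s_f\,\bigl(1 - t/(n\Delta t)\bigr)^3 , $$

which prunes aggressively while the network is redundant and gently near
the target. Cumulative filter targets are rounded half away from zero,
and since $s_{n\Delta t} = s_f$ exactly, each stage ends at exactly 50 %:
four stages take 64-filter blocks through 32, 16 and 8 to 4 filters, and
the 512-channel expansion to 32. The $\ell_1$ ranking is recomputed at
every iteration because weights keep moving between prunings (the
alternative — freezing the initial ranking — is cheaper but ignores
recovery during inter-iteration training). During pruning iterations the
learning rate is held constant at $10^{-4}$ with no annealing; after each
stage the network is fine-tuned for 15 epochs under the one-cycle policy.

Half-precision reduction rounds every conv and head weight to the nearest
IEEE 754 binary16 value (round-to-nearest-even, implemented bit-exactly),
while batch-norm parameters stay at FP32 for numerical stability. Memory
accounting for an FP16 model nonetheless uses a uniform 2 bytes per
parameter — the convention under which the reported footprints halve
exactly.

## Accounting conventions

`count_params()` counts conv weights + conv biases + 2 trainable
batch-norm parameters per channel + head weights and bias; batch-norm
running statistics are buffers, not parameters. This convention is forced
by the reference parameter counts it reproduces exactly (170,563 for the
full network; 11,923 with 16 filters; 1,063 with 4). Memory is
`params × bytes / 1024` kB. `count_macc()` counts
`out_length × in_channels × kernel × out_channels` per convolution under
"valid" padding, excluding elementwise work by default.

## Deployment model

The target platform is an 80 MHz Cortex-M4 class micro-controller
(128 kB SRAM): ~9 CPU cycles per FP32 multiply-accumulate, 10.2 mA
active draw, 1.6 µA in deep sleep. One inference per 90 s window
duty-cycles the device, giving an average current of
$(I_{act} t_{act} + I_{sleep}(T - t_{act}))/T$ — tens of µA — and a
battery lifetime of `capacity / current` on a 2600 mAh cell. The
accelerometer's own sampling current is excluded by default (it is a
property of the sensor, not the classifier) but can be added via
`sensor_current_uA`. All current figures in the package are µA.

```{r deployment}
report <- deployment_report(default_architecture(filters = 16),
                            input_length = 899,
                            reference = default_architecture())
report
```

## The synthetic herd

Real deployments train on weeks of halter-annotated farm data, which a
package cannot ship. The generator in `synth_config()` /
`generate_herd()` produces traces with the statistical structure the
method actually relies on:

* behaviour arrives in *bouts*: a semi-Markov chain with per-state
  exponential dwell (means 30 / 25 / 20 min for rumination / eating /
  other, truncated below at one minute), because behaviours last minutes
  and a per-sample Markov chain cannot produce that;
* rumination is an amplitude-modulated chewing oscillation (1.2 Hz) gated
  off for ~2 s at cycle intervals drawn from 40–60 s (the regurgitation
  pause); eating is the same oscillation at higher amplitude plus
  broadband head-motion bursts; other is quiescence with sporadic spikes;
* per-bout log-normal amplitude jitter makes eating and rumination
  overlap, so the learning problem is non-trivial and the dominant
  confusion is between those two classes, as on real farms;
* each axis adds an independent random-walk gravity offset (collar
  rotation) plus white noise, which is exactly what differencing must
  remove.

Default herd: 18 animals × 6 h. Six hours is the shortest duration at
which, given bout dwell times of tens of minutes, every animal reliably
exhibits all three behaviours — a precondition of per-animal balancing.
Analytic dwell-weighted stationary label fractions are available in
`stationary_label_fractions()` and the generator is tested against them.

What the generator does *not* emulate: biomechanical coupling between
axes, breed/diet variation, sensor saturation, halter mis-labels. Tests
passing on synthetic herds therefore demonstrate that the pipeline's
machinery (windowing, grouped CV, optimisation, pruning, accounting) is
correct, not that the default architecture reaches any particular
accuracy on real cattle.

## Numerical choices

* Convolutions run in single precision (the deployment precision) through
  im2col + GEMM kernels; a double-precision path exists and is used to
  verify analytic gradients against finite differences.
* Batch-norm uses $\epsilon = 10^{-5}$ and running-statistic momentum 0.1.
* Weight init is fan-in uniform with bound $1/\sqrt{\text{fan-in}}$,
  seeded; all stochastic steps (init, shuffling, dropout, undersampling,
  fold shuffling) derive from explicit seeds, and every function that
  seeds restores the caller's RNG state.
* Degenerate metric cases (0/0 precision/recall/F1) return 0 by
  convention; empty confusion-matrix rows are left as zero rows in the
  normalised matrix.
* Duplicated collar timestamps are rejected rather than averaged, since
  differencing over an averaged duplicate is ill-defined.

## Problem sizes used in the shipped checks

The package's own validation runs at desk scale, chosen as the smallest
sizes that still exercise every code path end to end: the pipeline check
trains the full 64-filter architecture on the default 18-animal herd
(5-fold grouped CV at 10 epochs — a reduced-epoch version of the 50-epoch
policy — with batch size 64, since a 256-window batch would give a
balanced desk-scale fold only a handful of optimisation steps per epoch),
and the pruning check runs two 50 % stages with 6 schedule iterations and
short fine-tuning on one fold's model. Full-scale settings
(50 epochs, 35 iterations, 4 stages, 15 fine-tune epochs) remain the
defaults in `train_config()` and `prune_config()`.

## Known limitations

* No sliding-window / overlap segmentation, no augmentation or
  oversampling: windows are contiguous blocks, balancing is by
  undersampling only.
* No quantisation below FP16, no low-rank factorisation or distillation.
* The MACC convention cannot be validated against an external reference
  because the reference stride/padding settings are unpublished;
  operation counts should be compared only within a fixed convention.
* `hyperparameter_search()` is a full grid — adequate for the intended
  3×3×3 grid, wasteful beyond it.
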