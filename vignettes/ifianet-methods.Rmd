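---
title: "Frequency-guided time-frequency networks for sEMG intent recognition: methods and design notes"
author: "ifianet"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Surface electromyography (sEMG) records muscle electrical activity through
skin electrodes; because neural activation precedes mechanical movement,
multichannel sEMG can be decoded into the *intended* locomotion mode of the
wearer — the key signal for lower-limb exoskeleton control. `ifianet`
implements a frequency-guided deep network for this task, together with the
full preprocessing chain, the conventional fusion baselines, ablation
variants, and a within-subject five-fold experiment protocol, all runnable
on synthetic data bundled with the package.

The classifier consumes 1200 ms windows of 8-channel sEMG sampled at
1000 Hz, each represented in two domains:

* a **scalogram** $|W(s, t)|$ from a complex-Morlet continuous wavelet
  transform on 30 log-spaced scales whose centre frequencies span
  450 Hz down to 20 Hz (the sEMG band), and
* a **one-sided FFT magnitude spectrum** (601 bins at $1000/1200$ Hz
  spacing), a global spectral prior insensitive to the time-frequency
  trade-off of the wavelet.

The encoder treats the 30 wavelet bands independently ("frequency-wise"
convolution): each band has its own three stages of a 3-tap temporal
convolution followed by 4-to-1 average pooling, taking the per-band
trajectory $1200 \to 1198 \to 299 \to 297 \to 74 \to 72 \to 18$ samples. An
aggregation convolution then mixes the 30 bands into 16 channels (kernel 3
along time), with BatchNorm and a Leaky-ReLU (slope 0.01), and the result is
rearranged into a 16-step sequence of $16 \times 8 = 128$ features (feature
index = aggregated-channel index $\times$ 8 + muscle index; the flattening
is frozen and covered by a permutation-equivariance test). A temporal
convolutional network (TCN) of three residual blocks — two causal dilated
convolutions per block, kernel 3, dilations 1/2/4, channels 128/256/128,
BatchNorm + ReLU, left-only padding with the overhang chomped — models the
sequence; its receptive field, $1 + \sum_\ell (k-1) d_\ell = 29$ steps,
covers the 16-step sequence. The decoder normalises the 2048 flattened
features, maps them to a 32-dimensional embedding (Leaky-ReLU, dropout),
and emits 17 class scores.

With every convolution carrying a bias and every BatchNorm affine, the
baseline (no frequency information) counts exactly 681,737 trainable
parameters, decomposing as 1,848 (band branch) + 609,664 (TCN) + 70,225
(decoder); the tests assert these closed-form sums layer by layer.

## The IFIA fusion module

The Frequency-Informed Integration Attention (IFIA) module injects the
global spectrum into the time-frequency stream at the stage-2 insertion
point (the $30 \times 74 \times 8$ block after the second conv+pool):

1. **Channel enhancement.** The frequency branch (two shared 3-tap
   convolutions and a 4-to-1 max pool: $601 \to 599 \to 597 \to 149$ bins
   per muscle) is flattened to 1192 features and passed through a
   squeeze-style MLP ($1192 \to \lfloor 1192/r \rfloor \to 30$, rectifier
   then logistic) producing one gate per wavelet band; the block is scaled
   band-wise by the gates. The reduction ratio defaults to $r = 4$.
2. **Temporal compression.** The gated block is averaged over time into one
   token per band and muscle — the global frequency modulation.
3. **Cross-domain interaction.** Per muscle channel, the 74 original
   time-step band vectors plus the compressed token go through multi-head
   self-attention (2 heads, width 64, weights shared across muscles,
   scaled dot product); the 74 outputs are projected back to 30 bands and
   added residually to the original block, and the compressed token's
   output is discarded. The insertion is therefore shape-preserving and
   stages 3+ of the encoder are untouched by the fusion choice.

Three ablations remove one operation each: `no_channel_attention` drops the
gating (the compressed token then summarises the raw block, so the spectrum
no longer influences the forward pass — the expected near-baseline
behaviour of this ablation); `no_cross_interaction` routes the gated block
straight to stage 3 (with all gates at 1 this is *exactly* the baseline,
which the tests verify bit for bit); `no_temporal_compression` lets all 74
gated tokens attend alongside the 74 original ones.

Three conventional fusion baselines complete the comparison set:
`data_level` resamples the spectrum to 1200 samples (linear interpolation)
and appends it as a 31st input band — because the band convolutions have
independent per-band weights, this adds exactly
$3\cdot(3+1) + 16\cdot 3 = 60$ parameters; `feature_level` concatenates the
1192 frequency features into the decoder input (decoder affine map
$3240 \to 32$); `decision_level` runs an independent frequency sub-network
(an affine lift $1192 \to 2048$ reshaped to a 16-step sequence, then its own
TCN and decoder) and averages class probabilities with equal weights. The
counted parameters preserve the ordering baseline $\le$ data-level <
feature-level < IFIA < decision-level. Where the exact reference
architectures of the feature- and decision-level baselines are not
recoverable from their printed totals, the package asserts only this
ordering.

## Preprocessing and labelling

The pipeline order is fixed: **filter → normalise → segment → transform**,
with the first two applied per trial. Filtering windows individually would
corrupt their edges, and a per-window 99th percentile would destroy
amplitude comparability across windows of one trial, so both operations are
trial-level by design.

* **High-pass filter**: 4th-order Butterworth, 20 Hz cutoff, applied
  forward–backward (`signal::filtfilt`), so it has zero phase and does not
  shift events relative to labels. DC and 5 Hz drift are attenuated below
  $10^{-6}$ and 10% respectively; a 100 Hz tone passes within 1%.
* **Normalisation**: each channel is divided by the 99th percentile of its
  absolute amplitude (linear interpolation between order statistics), so
  P99 = 1 afterwards; robust against transient artefacts compared with
  max-normalisation.
* **Segmentation**: windows of $W = 1200$ ms slide by $S = 200$ ms; a
  window starting at $t_0$ is labelled by the motion event active at its
  *label time* $t_0 + W + P_{\text{label}}$, the prediction look-ahead
  ($P_{\text{label}} = 100$ ms by default, swept 100–500 ms). Events are
  half-open $[\text{start}, \text{end})$; a label time exactly on an event
  boundary takes the later event, and the trial end belongs to the last
  event. A window whose label time leaves the trial (or falls in an event
  gap) is dropped; before pruning there are
  $\lfloor (L-W)/S \rfloor + 1$ positions, a formula property-tested
  against brute-force enumeration.
* **CWT**: complex Morlet with centre frequency 1.0 and bandwidth 1.5
  (config-exposed; the band count is fixed at 30 by the architecture),
  L2-normalised, evaluated by FFT convolution on a 2048-point grid padded
  beyond the slowest wavelet's support; magnitudes are returned. Scales are
  log-spaced so centre frequencies descend from 450 to 20 Hz; an 80 Hz tone
  peaks within one scale step of 80 Hz.
* **FFT**: real-input transform of the raw 1200-sample window, rectangular
  taper, magnitude spectrum. The one-sided doubling convention (interior
  bins doubled in power) reproduces the time-domain energy to $10^{-6}$
  relative (Parseval), and a 50 Hz tone lands in 0-based bin 60.

## Training protocol

Trials (not windows) are the cross-validation unit: per subject the trials
are shuffled and divided into five non-overlapping groups; fold $f$ takes
group $f$ (2 of 10 trials) as the test set and splits the remaining 8 into
7 training and 1 validation trial, rotating the validation trial across
folds — this reconciles the five-group rotation with the exact 7:1:2 ratio.
Because splitting is by whole trials, no window of a test trial can reach
training; a key-based leakage test enforces this.

Optimisation: mini-batches of 128, AdamW ($\beta = (0.9, 0.999)$, weight
decay $10^{-4}$, decoupled and applied to every parameter), initial learning
rate 0.003, reduce-on-plateau on the validation loss (factor 0.5, patience
5 — the policy's constants are config-exposed since only the policy itself
is prescribed), early stopping (patience 15 by default) and restoration of
the best-validation weights. The loss is softmax cross-entropy
$L = -\tfrac1N \sum_n \sum_i y_i^n \log \hat y_i^n$ with the logarithm
floored at $10^{-12}$. Decision-level fusion averages the two subnetworks'
softmax probabilities; the model returns $\log \bar p$ so that the standard
softmax-cross-entropy path recovers $\bar p$ exactly. Everything is seeded:
weight initialisation, batch order, dropout and the trial shuffle.

Metrics are accuracy (confusion-matrix trace over total) and macro-averaged
precision, recall and F1 over the classes present in the test labels; macro
averaging is chosen because minority-class recall is the behaviour of
interest in imbalanced locomotion data. Confusion matrices are
$17 \times 17$ with rows as true labels.

### Implementation note

No deep-learning runtime is part of the package's dependency footprint: the
forward passes and analytic backpropagation of every layer (band-wise
convolutions, pooling, BatchNorm, dilated causal convolutions, multi-head
attention, dropout, AdamW) are implemented natively, with the hot loops in
C++ (Rcpp/Armadillo, BLAS for the matrix products). Gradient correctness is
guarded by finite-difference checks during development and by behavioural
tests (causality, residual identity, seeded determinism) in the suite.

## The synthetic generator: what it emulates, and what it does not

Real multi-subject gait-lab corpora cannot ship with a package, so the
generator reproduces the *statistical structure the pipeline relies on*,
not the physiology: each of the 17 locomotion classes is a
`motion_class_spec` with a muscle-synergy gain pattern over the 8 channels,
a spectral support band inside 20–450 Hz, a cadence (0 for the static
postures Sitting and Standing), and a broadband noise floor. A channel's
signal is gain × envelope × band-limited Gaussian noise (zero-phase
4th-order Butterworth band-pass on white noise) plus floor × white noise.
Dynamic classes burst with a raised-cosine envelope at the cadence (duty
cycle 0.5, with a small tonic base), mimicking gait-cycle muscle bursting;
static classes have constant envelopes and lower gains, so their total RMS
is strictly below every dynamic class. Inter-subject variability is
multiplicative gain jitter $U(0.8, 1.2)$ and band-edge jitter of ±10 Hz —
an acknowledgement of electrode placement and impedance differences, not a
mechanistic model of them.

Amplitudes are arbitrary units by design (the reference corpus publishes no
quantitative amplitude description), which is immaterial downstream because
of the percentile normalisation.

Trials last 90 s at 1000 Hz and contain one segment per class in a
per-trial shuffled order. The default *quick profile* uses five
well-separated classes (Sitting, Standing, Walking, Ascending stairs,
Small steps in front), one subject and ten trials — sized so a CPU can
train the models in minutes. With the default specs, mean band-power
feature vectors of any two classes differ by more than three within-class
standard deviations (verified on 20 generated segments per class), so the
end-to-end experiment is well-posed; synthetic accuracies are therefore
*high* by construction and say nothing about accuracy on real recordings.
What the passing end-to-end tests do establish: the pipeline is wired
correctly, the optimiser trains every variant to convergence, the
trial-level protocol is leak-free, and increasing the prediction horizon
does not spuriously improve performance. They do not establish real-data
effect sizes, the ranking of fusion strategies on real sEMG, or robustness
to electrode shift and fatigue (deliberately not modelled).

## Numerical choices and degenerate inputs

* Percentiles use linear interpolation between order statistics
  (`quantile` type 7); an all-zero channel is rejected by name.
* BatchNorm uses biased batch variance, $\varepsilon = 10^{-5}$, and
  running moments with momentum 0.1 for inference.
* The TCN residual addition is **not** followed by an extra activation:
  zeroing all convolution weights and normalisation scales then reduces a
  block exactly to its residual path, a property the tests assert; with a
  post-addition ReLU this identity would not hold.
* Attention softmax subtracts the row maximum before exponentiation; with
  the output projection zero-initialised the module is exactly the
  identity, giving a safe warm start.
* Logistic gates saturate to exactly 0/1 in double precision beyond
  |logit| ≈ 745, which the limit tests exploit.
* Training-set scalograms are precomputed once per fold into a
  uint16-quantised store (one scale factor per band and window, relative
  error ≤ 1/65535 of the band maximum — far below the noise floor of the
  signals) and dequantised on the fly inside the first convolution stage;
  this keeps the memory footprint of a fold around 2 GB and the epoch time
  dominated by arithmetic rather than allocation.
* The experiment harness in the test-suite uses one fold of the five-fold
  split, a 30-epoch cap with early stopping (patience 3, minimum
  improvement $10^{-3}$), and, for the prediction-time trend, three
  training seeds at a fixed dataset and split with a two-epoch budget per
  run — problem sizes chosen so the whole study remains a desk-scale CPU
  computation; all are ordinary `train_config` settings, so the full
  protocol (all folds, patience 15, 100 epochs) is one argument away.

## Known limitations

* The frequency branch influences the `no_channel_attention` ablation's
  forward pass only through its (discarded) parameters, so that variant is
  the baseline plus attention on self-derived tokens — faithful to the
  ablation's design, but worth knowing when reading its accuracy.
* The exact reference parameterisations of the feature- and decision-level
  baselines and of the attention internals are under-determined by their
  printed totals; the package fixes documented, tested choices and asserts
  the reproducible invariants (the 60-parameter data-level delta, the
  count ordering) rather than unverifiable totals.
* The generator's classes are stationary within segments; transition
  dynamics between movements, electrode shift, and fatigue are out of
  scope.
* Training is single-threaded apart from BLAS; large-scale studies (many
  subjects, all folds, full 17-class profile) are possible but slow
  compared with GPU runtimes of the same architecture.
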