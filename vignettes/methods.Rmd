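---
title: "Joint reconstruction-classification models for ictal/interictal EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint reconstruction-classification models for ictal/interictal EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Scalp EEG during an epileptic seizure (the *ictal* state) differs from the
seizure-free (*interictal*) background in amplitude, rhythmicity and spatial
coherence. `ictalcae` implements a supervised convolutional autoencoder for
classifying fixed-length multichannel EEG segments into these two states with
minimal pre-processing: no filtering beyond the recording's native band, no
hand-crafted features.

A segment is an $I \times J \times 1$ value grid with $I = 256 \cdot s$
samples ($s \in \{1, 2, 4\}$ seconds at 256 Hz), $J = 23$ channels, and a
singleton depth axis so that 2-D convolutions over (time, channel) apply. The
encoder is four stages of

> convolution (3×2 kernel, stride 1, same padding, ReLU) →
> batch normalization → max pooling,

with 32, 64, 32, 64 filters and pooling windows (2,2), (2,2), (2,2), (2,3).
The time axis shrinks $256s \to 16s$ and the channel axis
$23 \to 12 \to 6 \to 3 \to 1$, giving a latent representation of
$16s \times 1 \times 64$. The decoder mirrors this with four
(convolution → activation → upsampling) stages, filters 64, 32, 32, 1, ReLU
activations except a final sigmoid, and upsampling factors (2,3) then three
times (2,2); the reconstruction is cropped back to the input grid.

Two classification heads read the latent code:

* **MLP**: flatten → dense 50 (ReLU) → dense 32 (ReLU) → dense 1 (sigmoid);
* **Bi-LSTM**: the latent's time axis is treated as a sequence of
  $16s$ steps with $64$ features; two independent 50-unit LSTM cells
  traverse it in opposite directions, their per-step hidden states are
  concatenated (100 features) and averaged over time, then a dense sigmoid
  unit emits the class probability.

The LSTM cell is the standard gated recurrence: forget, input and output
gates are sigmoids of affine maps of $[h_{t-1}, y_t]$, the candidate is a
tanh, the cell state is `forget * c + input * candidate`, and the hidden
state is `output * tanh(c)`.

Removing the decoder yields the classifier-only baselines, so four variants
exist (`DCAE_MLP`, `DCAE_BiLSTM`, `DCNN_MLP`, `DCNN_BiLSTM`); autoencoder and
baseline share a structurally identical encoder, and with equal seeds they
start from identical encoder weights, enabling controlled comparisons.

## Objectives

Autoencoder variants are trained against the weighted sum

$$TL = w_{cl} \cdot CL + w_{rlc} \cdot RC_L, \qquad
  w_{cl} = 0.5,\; w_{rlc} = 1.0,$$

where $CL$ is the binary cross-entropy of the predicted probabilities
(clamped to $[10^{-7}, 1-10^{-7}]$ before the logarithms) and $RC_L$ is the
mean squared reconstruction error, averaged per segment over the full
$q \times r$ value grid and then over the batch. Classifier-only variants
minimize the plain cross-entropy. Evaluation uses accuracy, sensitivity,
specificity, precision (each $\times 100$) and the F1 score computed as the
harmonic mean of fractional precision and sensitivity, rescaled to a
percentage. Ratios with an empty denominator are reported as 0 with a
warning rather than faulting, which keeps fold aggregation total.

## Data preparation

The pipeline order is fixed: extract → balance → z-score → min–max → depth
axis → fold assignment.

* **Extraction.** Segments are cut left-aligned and non-overlapping inside
  each qualifying region; trailing partial windows are dropped. Ictal
  regions are the annotated seizure intervals (events shorter than 10 s are
  excluded up front); interictal regions are the recording outside the
  seizure intervals enlarged by an exclusion buffer, 30 minutes by default,
  echoing the conventional preictal window, so peri-seizure data
  contaminates neither class. Intervals are half-open `[start, end)`
  seconds; samples are indexed from 0.
* **Balancing.** Interictal segments are down-sampled uniformly at random
  (seeded) to the ictal count.
* **Normalization.** Each channel is z-scored with mean and *population*
  (divide-by-n) standard deviation pooled over the entire merged dataset;
  a zero-spread channel has its sd replaced by 1 and maps to zeros. All
  values are then scaled together — one global affine map, not per channel —
  to $[0, 1]$, so original and reconstructed segments share a range that the
  decoder's sigmoid can produce. Both transformations are recorded
  (`channel_stats`, `scale_bounds`) and invertible via `denormalize()`.
  Computing the statistics on the merged dataset *before* fold splitting
  follows the preparation the models assume but leaks scale information
  across folds; `cross_validate(per_fold_normalization = TRUE)` recomputes
  them from the training folds only, for users who want the conservative
  variant.
* **Folds.** Stratified assignment by seeded per-class shuffle and
  round-robin: fold sizes differ by at most one and per-fold class balance
  is within one segment per class.

## Training protocol

Defaults follow the reference protocol: Adam (learning rate $10^{-4}$,
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-7}$), batch size 32,
per-epoch seeded shuffling with the last partial batch kept. SGD, RMSprop
and Adadelta are available as alternatives. The epoch count is not part of
the stated protocol and defaults to 100; early stopping is deliberately off.
Tenfold stratified cross-validation trains a freshly initialized model per
fold and reports each metric as mean ± standard deviation over the ten
held-out folds (per-fold-then-average, not pooled).

Weight initialization is seeded Glorot-uniform; biases start at zero. Batch
normalization uses $\epsilon = 10^{-3}$ and, in training mode, the
mini-batch's biased statistics; inference uses exponentially smoothed
running statistics. The running-statistics momentum defaults to 0.9: desk-
scale runs take only a few hundred optimizer steps, and a slower schedule
(e.g. 0.99) leaves the running estimates so far from the data statistics
that inference-mode normalization misrepresents the trained network. With
hundreds of epochs the momentum can be raised via `model_spec()`.

Dropout on the Bi-LSTM head defaults to 0 (the literal reading of the
configuration it reproduces); around 0.2 is a reasonable setting when
overfitting is observed.

## Numerical and design choices

* **"3-D" naming vs. data reality.** Segments are (time × channel × 1);
  convolutions are 2-D over the (time, channel) grid with a singleton depth
  axis. The stated 3×2 kernels and 512×23 matrices only cohere in this
  form.
* **Padding convention.** "Same" padding with stride 1; for even kernel
  extents, `floor((k-1)/2)` zeros before and the remainder after (a 3×2
  kernel pads one row above/below and one column on the right).
* **Pooling boundary mode.** Ceil-mode (partial boundary windows kept).
  Floor-mode would collapse the 23-channel axis to zero width after four
  pools, which is impossible, so the decision is forced; it is what makes
  23 → 12 → 6 → 3 → 1 work.
* **Upsampling semantics.** Nearest-neighbour repetition. It is exactly
  inverted by max pooling with the same factor, which keeps the
  encoder/decoder dimension arithmetic transparent; smooth interpolation
  would reconstruct marginally smoother signals but break that exactness.
* **Decoder crop.** After the final upsample the channel axis is 24; the
  trailing channel column is cropped to reach 23. The choice of which side
  to crop is arbitrary and documented as such.
* **Stage order in the decoder.** Convolution precedes upsampling in each
  stage, mirroring the encoder's convolution-before-pooling order.
* **Batch-norm placement.** Convolution (with ReLU) → batch normalization →
  pooling, i.e. the normalization separates each convolution from its
  pooling stage.
* **Precision.** The exported layer primitives (`nn_conv2d()` etc.) run in
  double precision and constitute the tested mathematical contract. The
  training engine instantiates the same templated C++ code in single
  precision — the standard precision of deep-learning practice — for speed;
  a dedicated test holds the engine to the composed double-precision
  primitives within $10^{-4}$.
* **Gradient correctness.** All backward passes (convolution, batch norm,
  pooling, upsampling, LSTM/BPTT, heads, losses) are hand-derived; during
  development they were verified against central finite differences of the
  double-precision engine to ~$10^{-5}$ relative error. End-to-end
  loss-decrease tests keep guarding them.
* **Decision threshold.** Probabilities ≥ 0.5 are called ictal (ties go to
  the positive class).

## The synthetic data generator

No public corpus ships with the package, so every stage is exercised on
synthetic recordings. Interictal data is zero-mean Gaussian background noise
(optionally 1/f-coloured); ictal data adds a sinusoidal burst at 4 Hz — the
spike-wave band of many generalized seizures — with amplitude
`background_noise_sd * (gain - 1)` on all channels with independent random
phases. A gain of exactly 1 removes the burst, making the two classes
distributionally identical (a useful degenerate test case); the default
gain 3 separates segment-mean absolute amplitudes in essentially every draw.
Continuous recordings embed such bursts in annotated intervals of at least
10 s placed uniformly at random without overlap, and can be written to EDF
with a plain-text annotation sidecar to exercise the real-data ingestion
path end to end.

What passing tests on this generator show is that the architecture, losses,
optimization and evaluation machinery work and that the models can learn an
amplitude/band-power-separable dichotomy; what they do not show is clinical
performance. Real ictal EEG has evolving spike-wave morphology, focal
topographies, artifacts and montage effects that the generator deliberately
omits; headline accuracies on synthetic data say nothing about patient data.

## Desk-scale problem sizes

The test suite and the acceptance script run the full method at sizes chosen
for a single CPU: 200 segments per class of 4-s data for the end-to-end
cross-validation (the learning problem is easy at gain 3, so 5 epochs at
learning rate $10^{-3}$ train to convergence — the protocol the package
documents as its desk-scale default), and 1-s segments with tens of
segments per class for unit-level training checks. The full-scale protocol
(hundreds of epochs at $10^{-4}$ on a full clinical corpus) uses the same
code paths through `train_config()` defaults.

## Known limitations

* No GPU path; throughput is bounded by single-threaded BLAS.
* Gradient-based training of very deep stacks on long (> 4 s) segments is
  untested; the architecture is fixed to the four-stage plan.
* The EDF reader/writer covers the subset of the format this pipeline needs
  (fixed-rate signals, 1-s records, 16-bit samples); it is not a general
  EDF+ implementation.
* Statistical comparison between model variants (significance testing) is
  out of scope; the grid report gives mean ± sd only.
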