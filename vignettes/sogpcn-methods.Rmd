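---
title: "Self-organizing graph pseudo-3D convolutional networks for EEG emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organizing graph pseudo-3D convolutional networks for EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Emotion recognition from multichannel EEG conventionally starts from
differential-entropy (DE) features: per electrode, per frequency band
(delta 1–3, theta 4–7, alpha 8–13, beta 14–30, gamma 31–50 Hz) and per
one-second frame, the Gaussian-assumption differential entropy
$\tfrac{1}{2}\log(2\pi e \hat\sigma^2)$ of the band-limited signal,
where $\hat\sigma^2$ is the band power estimated from a 512-point STFT
with a non-overlapping Hanning window. A trial is then an
$N \times M \times T$ tensor (electrodes × bands × frames). Trials from
film-clip protocols such as SEED run 185–265 frames and are zero-padded
at the tail to $T = 265$; the classes are negative, neutral and
positive emotion, and a 12-electrode bilateral temporal-lobe subset
(FT7, T7, TP7, P7, C5, CP5, FT8, T8, TP8, P8, C6, CP6) is the default
montage because the temporal lobes carry most of the discriminative
signal.

`sogpcn()` fits a network with four stages:

1. **Per-band self-organizing graph convolution.** For each band, the
   electrodes' DE time courses $V \in \mathbb{R}^{N \times T}$ are
   embedded as $G = \tanh(VW)$ ($W \in \mathbb{R}^{T \times L}$) and
   turned into an input-dependent adjacency
   $A = \mathrm{softmax}(GG^\top)$ — every electrode's outgoing weights
   are positive and sum to one. Each row keeps only its $k$ largest
   entries (top-$k$ sparsification, default $k = 10$; no
   renormalization afterwards), and a graph convolution
   $\mathrm{ReLU}(A_k V W_{gc})$ maps each electrode's 265-frame
   profile to 64 spatial features. Bands are processed independently
   with their own weights, so per-band connectivity structure is not
   mixed.
2. **Pseudo-3D spatiotemporal convolution with attention.** The stacked
   tensor (batch × 12 × 5 × 64 × 1) passes one full 3-D convolution
   (3 × 3 × 5 kernel, stride 1 × 1 × 3, 10 feature maps), then two
   blocks of factorized convolution — a 3 × 3 × 1 spatial factor
   followed by a 1 × 1 × 3 temporal factor, same-padded, ReLU after
   the pair — each followed by partial dot-product attention and
   2 × 2 × 2 average pooling. Attention scores each feature map from
   itself, $S = \chi M_1 M_2 + b$, softmax-normalizes along the frame
   axis and gates the map elementwise; parameters are shared across
   feature maps.
3. **Peephole LSTM.** The pooled tensor is read as a short sequence
   over its surviving frame axis (one flattened vector per frame) and
   unrolled through a peephole LSTM (input and forget gates read the
   previous cell state, the output gate the current one; peepholes are
   per-unit diagonal weights). Hidden size defaults to 64.
4. **Softmax classifier** over the final hidden state; training
   minimizes cross-entropy with Adam (learning rate 0.001, batch
   size 15, up to 200 epochs, dropout 0.1 on the LSTM output) and early
   stopping.

## Shape chain and resolved ambiguities

All stage extents are derived from the configuration arithmetic and
asserted against a real forward pass at build time
(`derive_shapes()`, `build_model()`). With the defaults the chain is

```
12 x 5 x 265  ->  12 x 5 x 64 x 1  ->  12 x 5 x 22 x 10
              ->   6 x 2 x 11 x 10 ->   3 x 1 x 5 x 10  -> sequence 5 x 30
```

Design points that the architecture description leaves open, and the
choices made here:

* **Softmax axis of the adjacency.** Row-wise: each electrode's
  outgoing weights normalize to one, making $A$ right-stochastic for
  feature aggregation. The alternative (column-wise) breaks the
  interpretation of a row as "the neighbors this electrode attends to".
* **Node features.** $V$ is the band's electrodes × padded-frames DE
  matrix, for both adjacency learning and convolution; this is the only
  choice consistent with the published 265 → 64 shape chain.
* **Graph propagation.** $A_k X W$ with ReLU; no self-loops or degree
  normalization are added since $A$ is learned and already
  row-normalized.
* **Entry-convolution padding** is 1 × 1 × 2, which preserves the
  electrode/band extents and reproduces the published intermediate
  temporal sizes (64 → 22 → 11 → 5 through the two pooling stages).
* **Pooling windows clamp to the axis extent** (`min(2, extent)` per
  axis), so single-band or few-band configurations — needed for the
  band sweep — remain well-formed instead of pooling an axis away.
* **Attention softmax axis** is the frame axis: the mechanism is meant
  to weight parts of the sequence. The bias $b$ carries no feature-map
  axis (parameters shared across maps).
* **No nonlinearity between the two pseudo-3D factors** (pure
  factorization); configurable in `pseudo3d_block()`.
* **ReLU vs tanh.** The network default is ReLU throughout (the
  architecture text); tanh is available via
  `sogpcn_config(activation = "tanh")`.
* **Peepholes** are diagonal per-unit weights, the standard peephole
  form; a non-peephole backend (`peephole = FALSE`) is available and
  the tests pin the reference cell against a scalar-loop oracle.
* **Flatten mode.** The pooled tensor feeds the LSTM as a sequence of
  per-frame vectors (`lstm_mode = "sequence"`), since a single-step
  flatten would make the recurrent layer pointless; the single-step
  mode remains available.
* **Embedding width** $L = 32$ and **LSTM hidden size** 64 are
  unstated upstream; both are configurable.
* **Top-k ties** break by ascending electrode index (stable selection);
  the batched training-path mask is tested to agree exactly with the
  reference implementation, including tied rows.
* **Early stopping** monitors validation loss with patience 20
  (restoring the best weights); the experiment harness holds out a
  class-stratified 15% of each training fold for this purpose.
* **Label coding.** Classes are handled internally as 0, 1, 2; the
  field's −1/0/1 (negative/neutral/positive) coding maps to 0/1/2 and
  fitted models predict in whatever coding the training labels used.
* **Ablation replacements** (`ablate()`): removing the graph module
  substitutes a per-band linear map $T \to 64$ (no adjacency); removing
  the pseudo-3D stack feeds the pooled graph output directly to the
  LSTM; removing attention is the identity. These are the minimal
  replacements that keep the remaining pipeline well-formed.

## Numerical implementation

The forward and backward passes are written in the package: base R
matrix algebra for the graph, attention and LSTM stages, and an
im2col + BLAS `dgemm` kernel (Rcpp) for the 3-D convolutions. Gradients
of every stage — including the softmax-adjacency Jacobian, the straight-
through top-k mask (gradients flow only through retained entries, the
standard subgradient at the selection), attention and the peephole
BPTT — are hand-derived and verified against central finite differences
in the test suite (`test-gradients.R`), for the full model and the
ablated variants. Softmax rows are computed with a row-max shift; DE
errors on zero band power are raised rather than silently clamped.

## What the synthetic generator emulates

`generate_dataset(synthetic_spec())` produces DE-level data with the
structure of the emulated recordings: 15 subjects × 15 trials, 12 or 62
electrodes, 5 bands, trial lengths uniform on 185–265 frames, balanced
classes. Signal structure:

* **Class-conditional mean shifts** of size `effect_size` (in noise-SD
  units, default 1) on the beta/gamma bands of the temporal-lobe
  electrodes, with symmetric class coding (−e, 0, +e) — mirroring the
  empirical finding that high-frequency bands discriminate best, which
  makes band-sweep results directionally comparable.
* **Inter-channel correlation** induced by mixing the noise through a
  planted ring-coupling graph of degree 10 (coupling 0.5, rows rescaled
  to preserve variance), so a top-k sweep has a recoverable optimum
  near $k = 10$.
* **Subject offsets**: constant per-subject electrode × band offsets
  (SD 0.3) emulating inter-subject variability.
* **Temporally structured mode** (`temporal_structure = TRUE`): the
  class signal becomes a class-specific temporal modulation
  (sinusoids at 1/3/5 cycles per trial) planted with alternating sign
  on adjacent electrodes, plus only a quarter-size static shift. The
  antisymmetric spatial contrast cancels under immediate 2 × 2 × 2
  average pooling but is recoverable by the pre-pool convolution
  stack — this is the construct the pseudo-3D ablation experiment
  probes, mirroring the direction of the published ablation in which
  removing that stack costs by far the most accuracy.

What it does **not** emulate: raw-EEG spectra (only DE-level
statistics), realistic inter-subject distribution shift, artifacts, or
session effects. Passing recovery tests therefore demonstrates that the
pipeline trains, discriminates planted structure, and respects its
protocols — not that real-data accuracies are reproduced (those require
the access-gated recordings and full-scale training).

## Experiment protocols and desk-scale sizes

`loso_cv()` implements leave-one-subject-out cross-validation (one fold
per subject, that subject's trials as the test set);
`subject_dependent_cv()` shuffles all trials and splits them into 15
near-equal folds. The sweeps (`band_subset_run()`,
`channel_subset_run()`, `topk_sweep()`, `ablation_run()`) accept a
protocol argument; besides the two cross-validation protocols there are
two single-split screening protocols, `"holdout"` (class-stratified,
the subject-dependent flavour) and `"holdout_subject"` (whole subjects
held out, the subject-independent flavour). Every experiment is
reproducible bit-for-bit from one master seed: per-fold seeds derive
from it, and it governs initialization, the validation split, minibatch
shuffling and dropout.

The packaged acceptance runs use desk-scale budgets chosen so the whole
battery completes on one CPU core in well under half an hour. Training
on this data passes through a characteristic loss plateau in which two
of the three (symmetrically coded) classes remain confused, so runs on
signal-bearing data use their full small epoch budget rather than
early stopping — a patience small enough to save time would fire inside
the plateau and freeze a fold at 2/3 accuracy; only the no-signal
chance-level runs keep early stopping (their level is insensitive to
it). Concretely: the LOSO recovery experiments run 14 epochs; the
ablation comparison runs 20 epochs on a subject-disjoint holdout
(4 of 15 subjects held out); and the top-k sweep runs 16 epochs on a
subject-disjoint holdout with 2 of 15 subjects held out — the larger
training set makes every sweep run converge, so differences between k
values reflect the planted structure rather than optimization noise,
and the sweep is read as a tie-margin check: k = 10 must sit within
two points of the best k. At the default effect sizes these budgets
put chance-level data at ~33% and strongly separable data above 90%
under LOSO.

## Known limitations

* The training loop is single-threaded R + BLAS; it is sized for the
  desk-scale experiments above, not for full-scale grid searches.
* MATLAB feature files are read through the system Python's `scipy.io`
  when available; the package's native on-disk format is the JSON
  fixture written by `write_features_file()`.
* The published headline accuracies on the gated recordings are out of
  scope; nothing in the package asserts them.
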