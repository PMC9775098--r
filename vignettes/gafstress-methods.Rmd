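---
title: "Stress classification from wearable channels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress classification from wearable channels: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gafstress)
```

## The problem

Chest-worn wearables record several slowly varying physiological channels
at once — three accelerometer axes, ECG, EMG, electrodermal activity,
skin temperature and respiration — together with a per-time-point stress
label (e.g. meditation / baseline / stress / amusement, or the
three-level no-stress / time-pressure / interruption labels of
office-stress studies). `gafstress` classifies the stress state of a
single time point from its cross-channel profile, by turning each
multichannel sample into a small image and training a compact
convolutional network on those images.

## The pipeline

1. **Group by label.** Rows are partitioned into contiguous per-label
   blocks (`group_by_label()`).
2. **Trailing window.** The final `window_size` rows of each block are
   kept (`take_last_n()`); 10,000 per class is the default for real
   recordings, which balances the classes by construction. A class with
   fewer rows than the window is an error, not a silent shrink (the
   `run_pipeline()` wrapper will shrink the window to the shortest class,
   with a message, as a convenience for exploratory runs).
3. **Quantile normalization.** Within each class block (default) or
   globally, every channel column is forced onto a common value
   distribution: sort each column, average across columns at each rank,
   and put the rank-r average back at the position of each column's
   rank-r value (`quantile_normalize()`). Ties receive the mean of their
   tied rank-averages — well defined, rank-preserving, and idempotent on
   tie-free input; exact idempotence under ties is impossible once a tie
   collapses the cross-column multiset equality. Whether the original
   procedure normalized per block or globally is not documented
   anywhere we could rely on; per block follows the narrative order
   (group, window, normalize) and the global variant is one flag away
   (`per_block = FALSE`).
4. **Image encoding.** Each row (one time point across `C` channels) is
   min–max rescaled to $[-1, 1]$, mapped to angles
   $\phi_i = \arccos(\tilde{x}_i)$, and expanded into the Gramian
   angular-sum matrix $G_{ij} = \cos(\phi_i + \phi_j)
   = \tilde{x}_i \tilde{x}_j - \sqrt{1-\tilde{x}_i^2}\sqrt{1-\tilde{x}_j^2}$
   (`gaf_encode_row()`). $G$ is symmetric, bounded in $[-1,1]$, with
   diagonal $2\tilde{x}_i^2 - 1$. The angular-difference variant
   $\sin(\phi_i - \phi_j)$ is available behind `method = "difference"`;
   the summation form is the default because its range and inner-product
   interpretation match the Gram-matrix construction, and it is the
   common default of the encoding's implementations. Inputs to
   $\arccos$ are clamped to $[-1,1]$ to absorb floating-point overshoot;
   constant rows map to the all-zeros vector. The Gram *determinant*
   plays no computational role anywhere and is not used.
5. **Split.** A seeded, stratified 3:2 train:test split
   (`test_fraction = 0.4`). Random splitting of contiguous streams lets
   near-duplicate neighbours straddle the split, which inflates accuracy
   on real recordings; a `temporal = TRUE` flag holds out the trailing
   rows of each class instead.
6. **Classifier.** The fixed architecture (`build_architecture()`):
   three valid (unpadded) 3×3 convolutions with 64 filters and ReLU,
   each followed by batch normalization, then 2×2 max pooling, a linear
   6-unit dense layer, and a softmax output of width `n_classes`. For an
   8×8 input the spatial sizes run 8→6→4→2→1 and the per-layer parameter
   counts are 640, 256, 36 928, 256, 36 928, 256, 0, 0, 390, 28
   (75 682 in total). Batch-norm counts include the moving mean and
   variance (4 per channel), the convention of standard framework
   summaries. The first dense layer is linear — unusual, but it is part
   of the fixed layer table this package implements, and the
   implementation follows that table literally. Inputs with side below
   8 are rejected: three valid 3×3
   convolutions plus pooling leave no spatial extent.

## Why the image side equals the channel count

One image is one *time point*: the `C` channel values of a row form the
vector that the angular encoding expands into a `C`×`C` matrix. The
8-channel chest modality therefore gives 8×8 inputs — exactly the input
size the architecture's printed shapes require. The alternative reading
(encode a time window of a single channel) is incompatible with those
shapes and is not implemented.

## Training

The network is trained by mini-batch gradient descent on categorical
cross-entropy (labels one-hot encoded), with Adam
(`learning_rate = 1e-3`, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$), batch size 32, per-epoch reshuffling, He-normal
initialization for the convolutions and Glorot-uniform for the dense
head, and batch-norm momentum 0.99 ($\epsilon = 10^{-5}$). Optimizer,
batch size and learning rate are not part of the fixed architecture;
these are the ubiquitous small-CNN defaults and are all exposed in
`gaf_cnn()` / `pipeline_config()`. There is no early
stopping. All convolutions are evaluated as im2col gathers followed by a
BLAS matrix product, in double precision; the backward pass is exact
backpropagation, verified against central finite differences in the test
suite. A single integer seed fixes initialization and shuffling;
`run_pipeline()` fans one master seed out to the generator, the split
and the training run.

Epoch counts: real-recording runs train for about 100 epochs; the
synthetic benchmark below converges well before 30, which is what the
packaged experiments use.

## The synthetic generator

`generate_synthetic()` produces what the pipeline structurally assumes:
`n_classes` contiguous label blocks of `points_per_class` rows ×
`n_channels` columns. Each class elevates its own channel subset
(`(channel - 1) mod n_classes == class`) by `class_separation` above a
fixed per-channel baseline, and adds a zero-mean sinusoid with `k` full
cycles per block for class `k` and a channel phase step proportional to
`k`, with amplitude `drift_amplitude * class_separation` (default 0.5),
plus i.i.d. Gaussian noise of `noise_sd`.

Two design points deserve explanation:

* **Constant offsets cannot carry the class.** Per-block quantile
  normalization forces every channel of a block onto an identical value
  distribution, and the row-wise encoding min–max rescales each sample;
  both erase channel *levels*. Any generator whose classes differ only
  in channel means produces a pipeline input in which the classes are
  unidentifiable (training memorizes, held-out accuracy sits at
  chance). The offsets are still generated — they make the
  class-conditional channel means differ by exactly `class_separation`,
  a property the tests verify — but the discriminative signal must live
  elsewhere.
* **The class is a spatial frequency.** The channel phase step makes
  class `k`'s cross-channel profile a sinusoid of spatial frequency `k`
  at every time point. Quantile normalization is a monotone map per
  channel and therefore preserves this joint structure, and a
  convolutional network separates spatial frequencies easily. Because
  the amplitude scales with `class_separation`, setting the separation
  to zero yields label-free noise and a chance-level classifier — the
  control condition of the packaged benchmark — and `noise_sd = 0`
  yields a fully deterministic stream.

What the generator does *not* emulate: physiological waveform morphology
(ECG complexes, EDA peaks), differing sampling rates, sensor drop-outs,
or between-subject variability. A pass on synthetic data therefore
demonstrates that the pipeline's machinery — normalization, encoding,
training, evaluation — recovers recoverable structure; it does not
certify accuracy on any real recording.

## Evaluation

`confusion_matrix()` uses rows = actual, columns = predicted.
Per class (one-vs-rest): precision $= x_p/(x_p+y_p)$, recall
$= x_p/(x_p+y_n)$, F1 $= 2/(1/\mathrm{precision} + 1/\mathrm{recall})$,
with $x_p, y_p, y_n$ the true-positive, false-positive and
false-negative counts. A class that is never predicted gets precision 0
with a warning instead of NaN. The per-class "accuracy" column of the
standard report table is not given a formula in the descriptions this
layout comes from; we report one-vs-rest accuracy (correctness of the
binary class-k-vs-rest decision over all samples) by default, with
`class_accuracy = "recall"` as the alternative reading. Averages are
unweighted macro means — with equal per-class windows the classes are
balanced, so macro and weighted averaging coincide. The overall
accuracy is $\mathrm{trace}(C)/\sum C \times 100\%$.

## Problem sizes and packaged experiments

The packaged benchmark (also what `scripts/acceptance.R` runs) uses
4 classes × 8 channels × 2,000 points per class, separation 3, noise
0.3, 30 epochs, 3:2 split — 8,000 images, 4,800 of them for training; a
run takes roughly two minutes on one CPU core. Under these conditions
the held-out accuracy is ≈ 99.6% with macro-F1 ≈ 0.996 (seed 1), and
the zero-separation control sits at 24–26%, i.e. chance for four
balanced classes. Unit tests use 40–100 points per class so the whole
suite stays fast.

## Known limitations

* No GPU path and no attention mechanisms; the engine is deliberately a
  faithful, compact CPU implementation of the fixed architecture.
* The architecture family is fixed; only input side and class count
  vary. Sides must be ≥ 8 (and odd sides lose a row/column at pooling).
* Real-recording loaders expect pre-aligned channels (decimate to the
  slowest rate first) and, for the per-subject chest records, a one-time
  conversion of the distributed serialization into RDS
  (see `?load_wesad_chest`).
* Real-dataset accuracies depend on an undocumented subject choice and
  split; the optional integration script
  (`inst/scripts/integration-real-data.R`) reproduces those runs only
  when local copies of the datasets are supplied.
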