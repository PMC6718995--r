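---
title: "Dual-path convolutional networks: shape calculus, sensor-to-image encoding, and the training harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-path convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualpathnet)
```

## The model family

The package implements a family of feedforward convolutional networks built
from *dual-path modules*: blocks with two parallel convolution branches whose
outputs are concatenated along the channel axis.

* A **normal dual-path module** runs a 1×1 and a 3×3 stride-1 convolution side
  by side on the same input. The output keeps the spatial size and has
  `filters(1×1) + filters(3×3)` channels. There is no identity shortcut: the
  printed channel arithmetic of the reference tables (e.g. 176 + 160 = 336)
  leaves no room for one.
* A **reduction dual-path module** pairs a 3×3 stride-2 convolution with a 3×3
  stride-2 max-pool. The pool branch has no filters, so it passes *all* input
  channels through; output channels are `filters(conv) + channels(in)` (e.g.
  96 + 336 = 432), and width/height halve.
* Every convolution is followed by batch normalization and a ReLU,
  `f(x) = max(0, x)`.
* The shared tail is global average pooling (one feature per channel),
  flatten, a fully connected layer with one neuron per class, and softmax.

Four architectures are bundled (`builtin_specs()`): `original` (64×64 input,
3×3 stride-1 stem), `reductive` (224×224 input with an aggressive 9×9 stride-3
stem), `deepened` (224×224, six extra modules with wider kernels before the
pool), and `revised_deepened` (the same six extra modules with the narrower
filter counts). The `revised_deepened` front is the 224-pixel, 3×3-stem module
sequence through the tenth normal module — the only front from which the
revised tail's printed 14×14 and 7×7 map sizes chain correctly.

## The shape calculus

For a square input the output width of a convolution or pooling window is

$$W_{out} = \left\lfloor \frac{W_{in} - K + 2P}{S} \right\rfloor + 1$$

with kernel width $K$, padding $P$ and stride $S$. Floor division is a design
decision, but not a free one: it is the only convention that reproduces the
full printed chains 224 → 74 → 37 → 19 → 10 and 224 → 112 → 56 → 28 → 14 → 7.
Padding is never stated in the reference tables, so the package fixes the only
paddings under which every printed cell is reproduced: $P=1$ for all 3×3
convolutions and pools (stride 1 or 2), $P=0$ for 1×1, and $P=2$ for the 9×9
stride-3 stem (any other value breaks the printed 74).

`infer_shapes()` chains this calculus over a declared architecture;
`audit_spec()` compares the result against the printed output-size cells
stored on each module. All four bundled specs audit with zero mismatches:

```{r audit}
specs <- builtin_specs()
sapply(specs, function(s) attr(audit_spec(s), "n_mismatch"))
sapply(specs, flatten_length)
```

One printed cell is treated as a typographical error: the deepened table's
thirteenth normal module prints "7 × 7 × 4160" where the channel arithmetic
(224 + 192) and the following rows require 416.

## Sensor specimens as images

A specimen is five numbers — doping-material code, angle, force, air pressure,
in-air current — plus a pollutant class (acetone, ethanol, chloroform,
toluene, methanol). The encoder renders a specimen as a 64×64 grayscale image
with five disjoint 20×20 zones, one per parameter, each filled with
`round(value × 255)`. Because a convolutional network sees position, two zones
with the same gray level still carry distinct information; that is the point
of the encoding.

The reference figure shows the five numbered zones but no coordinates, so the
layout here is one admissible realization: zones 1–4 in the four corners with
a 2-pixel margin and zone 5 (the in-air current, the most decisive parameter)
dead center. Any fixed non-overlapping layout preserves the method, since the
network learns the positions.

Two numerical conventions matter:

* **Normalization is max-scaling** (divide each parameter by its maximum over
  all specimens), not min–max. The stated constraint is only that values above
  1 would saturate to white; max-scaling satisfies it while preserving zero.
* **Quantization is round-half-up to 8 bits.** The mean zone intensity divided
  by 255 recovers the encoded value to within 1/255, and distinct quantized
  parameter tuples always produce distinct images.

Range-valued air pressures are the augmentation mechanism:
`expand_pressure_range()` replaces a specimen whose pressure is a range
`[low, high]` by `floor((high − low)/increment) + 1` copies at pressures
`low, low + increment, …`, with 295 Pa as the default step (147.5 Pa halves
the step and roughly doubles the images).

## Fundus-style preprocessing

`resize_shorter_edge()` (bilinear) followed by `center_crop_square()` turns an
arbitrary photograph into the square network input while keeping the eyeball's
aspect ratio; deliberately, no flipping, contrast enhancement or other
post-processing is applied. `class_distribution()` reports per-class counts
and percentages (half-up, two decimals); `split_dataset()` partitions a sample
table 0.9/0.1 by default, uniformly at random under a fixed seed.

## Training protocol

`build_network()` materializes a spec with Xavier-normal weights (variance
$2/(fan_{in}+fan_{out})$), zero biases, unit batch-norm gains. Convolutions
carry no bias of their own — the batch-norm shift immediately follows, and a
zero-initialized conv bias would be redundant with it. `train_network()` runs
minibatch SGD on the softmax cross-entropy with:

| parameter | default | note |
|---|---|---|
| learning rate | 0.01 | multiplied by 0.1 at the decay epochs |
| momentum | 0.9 | classical (non-Nesterov) |
| weight decay | 0.0005 | conv and FC weights only, never batch-norm/biases |
| decay epochs | ⌈E/2⌉, ⌈3E/4⌉ | conventional two-step schedule; configurable |
| batch size | 7 | presets used historically: 56, 68, 7 |
| batch-norm | ε = 1e-5, momentum 0.9 | framework-conventional |

The engine represents activations as `(N·H·W) × C` matrices; convolutions are
im2col (C++) plus BLAS matrix products, so the whole backward pass is exact
(verified against central-difference gradients during development) and fast
enough for single-CPU use. A `width_multiplier` scales every filter count
(minimum 1) so the architecture *shape* can be trained faithfully at desk
scale; 0.25 turns the original network's 336 pooled features into 84.

The first batch of every run is shape-audited at runtime against
`infer_shapes()`, and training aborts with a diagnostic on a non-finite loss.
Given one seed, building, shuffling and training are bit-reproducible.

## Activation analysis

`extract_activations()` returns the global-average-pooled feature vector per
sample (336-dimensional for the original and reductive networks,
416-dimensional for the deepened one). Since features are averaged ReLU
outputs, a column is **exactly zero** over a sample set if and only if its
filter never activated — so the dead-unit census (`count_dead_units()`) uses
exact zero, no epsilon.

`embed_3d()` projects the pooled features to three dimensions with t-SNE for
visualization. No t-SNE implementation ships with the R stack this package
targets, so the package includes its own: conditional Gaussian affinities
calibrated to the target perplexity by bisection, symmetrized, early
exaggeration ×4 for the first 50 iterations, and 500 momentum gradient-descent
steps (0.5 → 0.8 at iteration 250, learning rate 200, gain adaptation). The
default perplexity is `min(30, n/4)`. The embedding is deterministic under a
seed; as with any t-SNE, between-cluster distances are only qualitatively
meaningful.

## Synthetic data: what it does and does not emulate

The sensor generator (`gen_sensor_specimens()`) draws Gaussian clusters around
five per-class parameter means (`default_class_means()`): doping codes 1–5,
angles 15–75°, forces 2–8, pressures 40–100 kPa, currents 18–86 instrument
units. Defaults are **150 specimens** (30 per class, round-robin) and
**noise_sd = 0.05** — noise with standard deviation 5% of each parameter's
scale, applied to all five parameters and clipped at zero. These defaults are
the package's study conditions for the end-to-end tests: with them, encoding
the specimens and training the original architecture at width multiplier 0.25
for 30 epochs reaches at least 0.9 validation accuracy on the held-out 10%.

What the generator deliberately does *not* emulate: correlated parameters,
instrument drift, heavy-tailed noise, label noise, or class imbalance. Passing
the end-to-end test therefore shows that the pipeline — encoder, network,
optimizer — can carry separable five-class structure end to end; it says
nothing about accuracy on any real apparatus, whose specimens and pressure
ranges are not published and whose printed dataset sizes (537 and 993 images)
consequently cannot be regenerated.

The toy fundus generator (`gen_toy_fundus()`) produces a dark field with a
bright disk and class-dependent counts of small bright spots (non-decreasing
in severity class). It exists so the resize/crop/split/train plumbing is
testable on class-structured RGB images; it is not a retinal simulation.

## Problem sizes and numerical choices in the tests

The test suite trains only desk-scale models: the two-class smoke tests use a
16×16 five-module architecture, and the five-class end-to-end property uses
the original 64×64 architecture at width multiplier 0.25 on the 150-specimen
default set (135 train / 15 validation, 30 epochs, batch 7, seed 1). The
sliding-window oracle for the shape formula enumerates ~2,200 parameter
combinations; the dead-unit census is cross-checked against an explicit column
scan on 100 random matrices. Ties in `predict()` break toward the lowest class
index; the train/validation split uses `floor` for the train size; percentage
rounding is half-up (the reference distribution table itself mixes rounding
and truncation in its last two rows, so only its first three percentage cells
are asserted exactly).

## Known limitations

* CPU-only, dense `double` arithmetic; full-width 224-pixel trainings are out
  of desk scope (use `width_multiplier`).
* Batch-norm statistics with batch size 7 are noisy; the running statistics
  used at evaluation time smooth this but small batches remain a source of
  run-to-run variation across platforms (not across runs with one seed).
* The 42-layer count quoted for the family depends on a counting convention
  (whether normalization/activation count as layers) that cannot be
  reconstructed; the package counts modules instead.
* `dual_cnn` checkpoints are RDS files: portable across platforms, but not
  across incompatible package versions.
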