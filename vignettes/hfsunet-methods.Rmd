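---
title: "HFSUNet: model, loss and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HFSUNet: model, loss and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pneumonia lesions on CT — ground-glass opacities in particular — are
low-contrast blobs with blurred, irregular boundaries, embedded in a
textured background that dominates the image area. Two failure modes hurt
standard UNet-style segmenters here: (i) pooling-based downsampling erases
small lesions (a component under 100 pixels can shrink to 1–2 pixels, or
nothing, by the bottleneck), and (ii) pixel-uniform cross-entropy lets the
easy background drown out the gradient signal from the hard boundary band.

HFSUNet is a lightweight UNet variant addressing both with three
components: Haar wavelet downsampling (HWD), a multi-scale attention module
(MSAM) on the skip connections, and a morphology-weighted boundary loss
(MWL). This package implements the model and its full training/evaluation
stack in R, including a CPU reverse-mode autodiff engine, because no deep
learning framework is part of the package's dependency footprint.

## Haar wavelet downsampling

The single-level 2-D Haar transform under the *averaging* convention
computes, per 2-pixel pair, `L = (x0 + x1)/2` and `H = (x0 - x1)/2`, first
along rows and then along columns of both results, yielding four
half-resolution subbands `ll, lh, hl, hh`. Key consequences we exploit (and
test):

* `ll` equals 2×2 average pooling exactly — so HWD subsumes average pooling
  while additionally retaining the three detail subbands;
* the transform is exactly invertible (`x0 = L + H`, `x1 = L - H`), so no
  information is lost at the downsampling step — what survives to the next
  level is decided by a learned fusion, not by the resolution change;
* the energy identity is `4 * sum(ll² + lh² + hl² + hh²) = sum(x²)` (the
  orthonormal convention with `1/sqrt(2)` factors would drop the 4; we use
  the averaging convention because the `ll`/average-pooling equivalence is
  the property that matters for a pooling replacement).

The HWD block stacks the four subbands channel-major (`ll, lh, hl, hh` per
input channel, giving `4C` channels at half resolution — this order is
fixed so checkpoints are portable) and fuses them with a convolution +
batch normalization + ReLU down to the configured output width. The fusion
kernel defaults to 1×1: the subband stack already encodes a 2×2 spatial
neighborhood, so a pointwise mix is the cheapest sensible choice; the
kernel size is configurable for wider context.

The transform primitive itself (`haar_dwt_2d`) rejects odd-sized inputs to
keep the math exact; padding is the caller's concern. At the network level,
`predict_mask()` reflect-pads any input whose size is not divisible by
`2^(levels-1)` and crops the prediction back.

## Multi-scale attention on skips

Skip tensors carry fine spatial detail but also background clutter. MSAM
refines them with two branches and a residual add:

* **spatial branch** — pointwise compression by `compression_ratio`
  (default 4), three parallel depthwise convolutions at kernel sizes 3, 5,
  7 (defaults; anything odd works), summed, then BN + ReLU, then a
  pointwise projection and a sigmoid producing a single-channel spatial
  attention map. Summation (rather than concatenation) keeps the compressed
  width fixed regardless of how many scales are configured; BN is applied
  once to the merged tensor. The map is broadcast across channels by
  default; a per-channel map is available (`spatial_per_channel = TRUE`).
* **channel branch** — global average pooling, then a two-layer pointwise
  bottleneck (`channel_bottleneck_ratio`, default 4) ending in a sigmoid,
  giving one weight per channel per sample. The bottleneck activation is a
  leaky rectifier (slope 0.01) rather than a strict ReLU: with a strict
  ReLU the whole squeeze layer can initialize dead (all pre-activations
  negative — we observed this at small widths), which silently severs the
  gradient path to its weights. The leak makes "every parameter receives
  gradient" a structural property instead of an initialization lottery.
* **fusion** — a pointwise convolution lifts the compressed multi-scale
  features back to the input width; the output is
  `out = x + channel_att ⊙ (spatial_att ⊙ fused)`. Spatial weighting is
  applied first, then channel weighting, then the residual add. Because
  both attention maps lie in (0, 1), the perturbation is bounded by the
  fused branch (`|out − x| ≤ |fused|` elementwise), and zeroing the fusion
  weights reproduces the input exactly — both are tested.

## Network assembly

Four resolution levels by default (so three HWD stages), base width 32
doubled per level, double-conv (3×3 + BN + ReLU, twice) per level, MSAM on
each skip, decoder mirroring the encoder with bilinear ×2 upsampling + 3×3
convolution (a learned 2×2 stride-2 transposed convolution is available via
`upsample_mode = "transposed"`), and a 1×1 convolution + sigmoid head for
binary masks (threshold 0.5). Convolutions followed by BN carry no bias —
BN's mean subtraction makes such biases exactly non-identifiable.

The reference implementation of the published model reports 5.638 M
parameters and 11.582 GFLOPs, but the exact widths/depth and the input
resolution behind those figures are not recoverable from the description;
we therefore expose depth and width as configuration and report our own
analytic counts (`count_parameters()`, `estimate_flops()`) rather than
claiming equality. The FLOPs estimate is an analytic per-layer sum (2 FLOPs
per multiply-accumulate; BN folded to a per-element affine) in which
convolutions dominate.

## Marginal weight loss

For a binary ground truth `GT`, erosion and dilation with a square
structuring element define three regions: interior `W_e = erosion(GT)`,
margin band `W_d − W_e` with `W_d = dilation(GT)`, and background
`1 − W_d`. Since `W_e ⊆ GT ⊆ W_d`, the three indicators partition the image
(tested property). The weight mask is

```
weights = w_b * (1 - W_d) + w_m * (W_d - W_e) + w_0 * W_e
```

and MWL is the weighted binary cross-entropy. Choices made here, all
configurable:

* structuring element 3×3, one iteration, zero-padded borders (so the
  margin band is the 8-neighborhood boundary ring on each side of the
  contour);
* default region weights `w_b = 1, w_m = 2, w_0 = 1` — the margin is
  up-weighted relative to interior and background; the published
  description states the principle ("higher weights" on the boundary) but
  prints no values, so these defaults are ours;
* the exact summed form is available (`reduction = "sum"`); training
  defaults to the pixel-mean form so the learning rate does not depend on
  image size;
* probabilities are clamped at `eps = 1e-7` before the logs; the analytic
  gradient is flat where the clamp is active (verified against central
  finite differences at 1e-4 relative).

With unit weights MWL reduces exactly to binary cross-entropy, which is the
cross-check used in the tests. CE and soft-Dice losses are provided as
ablation baselines.

## Metrics

All metrics derive from pixel confusion counts and are reported in percent:
mIoU (mean of foreground and background IoU), Dice `2TP/(2TP+FP+FN)`, F1,
and accuracy. Two conventions worth stating:

* **empty classes** — when a class is absent from both the ground truth and
  the prediction, its IoU/Dice is scored 100% (a lesion-free slice
  predicted clean should not be penalized); configurable to 0 or NA.
* **F1 vs Dice** — the pixel-level (micro) foreground F1 is algebraically
  identical to Dice, yet published tables often report them as different
  numbers, which implies some unstated aggregation. We implement micro
  (= Dice) and a macro-over-classes variant and leave the choice explicit
  rather than guessing.

Dataset-level aggregation is provided both micro (summed counts) and macro
(mean of per-image values); per-image macro is the default reporting
aggregation since the paired model comparison needs per-image values.
Connected lesion components use 8-connectivity (the blob-lesion
convention); components under 100 pixels are flagged small, and evaluation
reports how many small ground-truth components the prediction touches at
all (detected vs missed).

## Paired model comparison

Given per-image scores of two models on the same test images, the stats
module computes descriptive summaries (sample SD, n−1 denominator;
SE = SD/√n), a one-tailed paired t-test in the fixed direction "model B
exceeds model A" (`t = mean(d)/(SD(d)/√n)`, df = n−1), and Cohen's d for
paired data (`mean(d)/SD(d)` — the n−1 SD is required to reproduce the
published effect size from the published mean/SD). Zero-variance
differences are flagged as degenerate rather than producing silent
infinities. The report includes three diagnostic panels (difference
histogram with mean line, arm boxplots, paired scatter against `y = x`)
plus the fraction of images strictly above `y = x` and the fraction of
large differences (|d| above a threshold) that are positive. Summary-based
entry points (`paired_t_from_summary`, `cohens_d_from_summary`) allow the
same computations directly from a printed summary table.

## Synthetic data

The generator emulates what makes this segmentation problem hard, without
any external data: a smooth low-frequency background (bilinear upsampling
of an 8×8 uniform field in [0.15, 0.45]) plus Gaussian pixel noise
(SD 0.05); lesions as unions of random ellipses with a small intensity
offset (default 0.25) whose *image* profile is Gaussian-blurred (σ = 1.5 px)
while the *mask* stays crisp — i.e. low-contrast, blurred-boundary targets;
and a configurable fraction of images (default 0.3) carrying a separate
connected component under 100 pixels, placed with a one-pixel gap from
other lesions so it remains its own component. Defaults were chosen once to
look like the low-contrast ground-glass regime and are not tuned to any
test outcome; identical seeds reproduce datasets byte-for-byte, including
the written PNGs.

What the generator does *not* emulate: HU calibration and lung windowing,
anatomical context (vessels, airways, pleural boundaries), consolidation
textures, and inter-slice correlation. Passing tests on this phantom
demonstrate that the optimization and evaluation machinery is correct and
that the model can fit low-contrast blurred-boundary targets; they say
nothing about clinical performance on real CT.

## Training protocol and numerical choices

Training follows the published protocol: RMSprop (smoothing constant 0.99,
eps 1e-8), initial learning rate 1e-4, batch size 8, a budget of 1000
optimizer steps ("steps" read as optimizer steps, not epochs), early
stopping with patience 50. The description names the patience but not the
monitored quantity or frequency; we monitor validation mIoU every 50 steps
by default and keep the best-validation snapshot. Augmentation (each with
probability 0.5: horizontal/vertical flips, scaling U(0.8, 1.2), random
crop to a U(0.8, 1) window resized back, contrast gamma U(0.8, 1.2)) uses
magnitudes of our choosing — the published list names the transforms but no
ranges. Geometric transforms are applied identically to image and mask;
masks are interpolated nearest-neighbor and stay binary.

Other numerics: He-normal initialization for convolution weights; BN with
eps 1e-5, momentum 0.1, eval mode using running statistics; one global seed
drives model init and the batching/augmentation stream, so runs are exactly
reproducible; checkpoints store the config, all parameter arrays in a
deterministic collection order, and BN running statistics — a save/load
round-trip reproduces evaluation metrics bit-for-bit.

The test suite exercises training at desk scale by choice: the overfit
sanity check fits 4 synthetic 64×64 images with a 3-level, base-8 model for
at most 500 RMSprop steps at lr 1e-4 and requires dataset Dice ≥ 0.90, and
the end-to-end pipeline check runs a 20-image dataset with 2-level models
for 60 steps per loss arm. These sizes verify gradient flow through HWD and
MSAM and full-pipeline determinism; they are not benchmark runs.

## Known limitations

* CPU-only and written for clarity at small scale; wall-clock cost grows
  quickly with width and resolution compared to GPU frameworks.
* Binary (single-foreground) segmentation only; no deep supervision, no
  pretrained weights, no multi-level wavelet pyramids, no distance-based
  boundary losses or surface-distance metrics (HD95/ASSD).
* The published benchmark figures on external CT/ultrasound datasets are
  out of reach by design here — they require the original data and
  GPU-scale training; this package reproduces the method, its properties,
  and the published paired-statistics analysis, not those tables.
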