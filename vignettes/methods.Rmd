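---
title: "Growth-stage detection: model, training procedure and accounting conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-stage detection: model, training procedure and accounting conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soystage)
```

`soystage` detects the nine ordinal soybean growth stages (VE, VC, V1, V2,
V3+, R1–R2, R3–R5, R6–R7, R8) in RGB images. This vignette is the package's
account of the model it implements, the training and evaluation procedures,
the parameter and FLOP accounting conventions, and the design decisions
taken where the design was genuinely open. Everything quantitative shown
here is computed by the package at build time of this document or asserted
by the test suite; nothing is transcribed from elsewhere.

## The detection model

**Backbone.** A compound-scaled inverted-bottleneck convolutional network.
A scaling coefficient φ expands depth, width and resolution as
d = α^φ, w = β^φ, r = γ^φ under the constraint α·β²·γ² ≈ 2 (so the cost of
one φ step is roughly a doubling); the implementation uses the canonical
bases α = 1.2, β = 1.1, γ = 1.15 and the canonical per-variant width/depth
multipliers, since the constraint alone does not identify them. Widths snap
to multiples of 8 with a 90% floor; depths round up. Each MBConv block is a
1×1 expansion by ratio *t*, a k×k depthwise convolution (stride 1 or 2,
ceil-mode padding), a squeeze-and-excitation gate whose bottleneck width is
a quarter of the *block input* channels (rounded up), a 1×1 projection, and
a residual exactly when stride is 1 and channel counts match. Swish (SiLU)
activations and batch normalization follow every convolution except the
projection's activation.

The detection backbone is **truncated**: the stem and the seven MBConv
stages. The conventional final 1×1 expansion conv (and classifier) is not
part of the feature path. This truncation is what makes the per-variant
parameter counts land exactly on their reference values:

```{r}
sapply(c("B3", "B5", "B7"), function(v) round(backbone_param_count(v) / 1e6, 2))
```

The model nevertheless *retains* the final expansion conv as a
"checkpoint-compatibility" component (`compat.*` in the parameter
registry): image-classification checkpoints then load without surgery, and
the component is never executed during detection (it contributes zero
FLOPs). This has an accounting consequence discussed below.

Features are tapped at the last block of each stride — stride 4/8/16/32 map
to canonical stages 2/3/5/7; the detector consumes strides 8–32 by default,
with the stride-4 stage available for the four-level ablation.

**Neck.** A channel mapper, deliberately simpler than a feature pyramid
network: per-level bias-free 1×1 convolutions to 256 channels, group
normalization (32 groups × 8 channels, ε = 10⁻⁵), and one extra stride-2
3×3 convolution producing P6 from P5 (also bias-free + GN). Because the
mapping convs carry no bias, the mapping parameter count is exactly
`sum(C_i × 256)`; for the B7 channel set:

```{r}
neck_param_count(neck_config(c(`3` = 80, `4` = 224, `5` = 640)))
```

With the stride-4 stage enabled the neck maps four levels and still appends
P6, giving a five-level pyramid; the head consumes whatever levels the neck
provides.

**Head.** The flattened pyramid (sine positional + learned level
embeddings) passes through `E` encoder blocks of multi-scale deformable
self-attention — each query samples a small set of learned offset locations
per level instead of attending densely — followed by an FFN, both with
residual + layer norm. Object queries (300 learned content embeddings) are
initialized two-stage style: a proposal branch scores every encoder token
and the top-k proposal boxes become the initial references. Each of `D`
decoder blocks applies masked self-attention, box-modulated deformable
cross-attention, and an FFN; a per-layer regression MLP refines the
reference in inverse-sigmoid space (references are detached between
layers). The predictors are **task-aligned**: the classification branch
sees `Q + 0.1·tanh(Q)` and the regression branch `Q + 0.1·σ(Q)` — two
cheap, bounded (≤ 0.1 elementwise), differently-curved views of the shared
query that decouple the two tasks' gradients; both MLPs use a narrow hidden
width of 128 (half the embed width) for parameter economy. Presets pair
backbone and depths as small = B3 + 2/1, medium = B5 + 3/1,
large = B7 + 3/3.

Hyperparameters the architecture description leaves open were fixed once:
8 attention heads, 4 sampling points per level, FFN width 1024, 300
queries, dropout 0. A calibration test documents the parameter totals these
choices produce.

## Training procedure

**Losses.** Classification uses the quality focal loss with β = 2 and an
IoU-aware target: for a matched query the target at the ground-truth class
is the IoU between the current layer's (post-refinement) predicted box and
its ground truth, zero elsewhere. The canonical form
−|y−σ|^β((1−y)log(1−σ) + y·log σ) is the default; the self-entropy variant
(σ inside both logs) is selectable (`qfl_form = "as_printed"`) but is
degenerate as a loss — it vanishes for any confident score regardless of
the target — so it is not used for training. Localization is
5·L1 + 2·(1−GIoU) on normalized (cx, cy, w, h). Matching is minimum-cost
bipartite assignment (shortest-augmenting-path Hungarian) under
2·focal-class-cost + 5·L1 + 2·(1−GIoU); every decoder layer and the
encoder-proposal stage carry auxiliary losses.

**Adaptive denoising.** Each ground truth is copied into `G` noise groups
(default 3) with class-frequency scales α_c = 1.5 − n_c/n_max ∈ [0.5, 1.5):
the most frequent stage gets 0.5, rare stages approach 1.5. Labels shift by
a discrete uniform on ±⌊2α_c⌋ — clamped to the 0–8 ordinal scale so
perturbations respect phenological adjacency at the ends — and boxes move
by α_c·η·u with u ~ U(−1,1)⁴, η = 1, clamped to valid normalized boxes.
Noise queries are bound to their source ground truth (no matching), use the
same losses, and are isolated by an attention mask that blocks all flow
between groups and between noise and matching queries in both directions.
Only positive (reconstruction) queries are generated; contrastive negatives
are left as a toggle point. With adaptive scaling disabled all classes use
a fixed scale.

**Optimization.** AdamW (β = 0.9/0.999, weight decay 10⁻⁴, skipped for
biases and norm affines), base rate 2·10⁻⁴, linear warmup from 0.1% over
the first 1000 iterations, ×0.1 decay at epochs 30 and 40 of a 50-epoch
schedule, a 0.1 multiplier on backbone (and compat) parameters, and global
L2 gradient clipping at 0.1. Batch normalization uses batch statistics
during training and momentum-0.1 running statistics at inference;
`refresh_bn_stats()` performs an exact one-pass re-estimate after the final
weight update (the momentum average lags the weights), which `run_train()`
applies automatically before validation and on completion. Augmentation is
random horizontal flip (boxes mirrored exactly), isotropic scale jitter
(0.8–1.2), and photometric brightness/contrast/saturation/hue jitter with
documented default magnitudes — these magnitudes are this package's
constants, not empirical claims.

All numerics, including the reverse-mode differentiation the training loop
uses, are implemented in the package over plain R arrays; gradients of
every primitive are verified against central finite differences in the
development checks, and the structural invariants (residual identity,
normalization moments, reference-box ranges, mask structure) are enforced
by the test suite.

## Evaluation protocol

COCO-style average precision: IoU thresholds 0.50:0.05:0.95, greedy
per-image matching in score order, 101-point interpolated precision,
classes without ground truth excluded from the mean; confidence threshold
0.05, class-wise NMS at 0.5 IoU (applied in the harness even though a
set-prediction head can operate without it; toggleable via the protocol),
at most 100 detections per image, 512² evaluation resolution. Scale buckets
split on bounding-box area at 32² = 1024 px² and 96² = 9216 px² with strict
lower bounds. The evaluator is cross-checked in the tests against an
independently written scalar-loop implementation of the same protocol to
10⁻⁶ on random small instances.

## Parameter and FLOP accounting

`count_params()` reports the registry totals per component. Two conventions
matter:

* The **backbone** figure counts the truncated feature path only (stem +
  stages). The retained compatibility conv is reported as its own
  component and therefore lands in the "everything outside the backbone"
  remainder that `neck_head_params()` returns. This mirrors how deployed
  detection stacks count: the backbone column reflects the feature
  extractor's published size, while the model as shipped still carries the
  checkpoint-compatibility weights. For the large preset the remainder is
  8.29 M (neck 0.83 + head 5.82 + compat 1.64).
* **FLOPs** follow the one-MAC-equals-one-FLOP convention at a stated input
  size: convolution cost `C_in·k²·C_out·H_out·W_out`, linear cost
  `d_in·d_out·L`, attention sampling ≈ 5 MACs per sampled dimension, plus
  the self-attention bilinear forms. Element-wise work (activations,
  normalizations, gating) is tallied separately and excluded from the
  headline figure, so either convention can be reported. The profile is
  analytic — computed from layer shapes, not by timing — and the neck rows
  are cross-checked against the closed forms `Σ Cᵢ×C_out` and
  `Cᵢ×C_out×Hᵢ×Wᵢ` in the tests. FLOP totals scale with input *area*; at
  512² the large preset costs

```{r}
count_flops(soystage_model("large"), 512L)
```

The efficiency score is AP / (w_p·Params/100M + w_f·FLOPs/10G) with
w_p = 0.2, w_f = 0.8 — FLOPs dominate because sustained compute, not
memory, binds on agricultural edge hardware — normalized to a configurable
baseline triple (default: the strongest transformer baseline in this
model family's comparison set, 74.7 AP / 63.5 M / 102.5 G). Raw and
normalized values are always reported together, since the normalized value
depends entirely on the chosen baseline.

## The synthetic scene generator

The generator emulates the *structure* of single-plant greenhouse imagery,
not its appearance: per-class image frequencies follow the reference
distribution (17,204 images across nine stages, most frequent R6–R7 with
3,810, rarest VE with 307); one plant per image by default (multi-plant
scenes are available but are outside the single-plant capture setting the
defaults model); object size grows with the phenological ordinal (emergence
scenes land in the medium area bucket, maturity scenes are large with high
probability); a 2% miniature fraction keeps the sub-1024 px² bucket
non-degenerate, mirroring datasets of this kind in which genuinely small
objects are rare; backgrounds, lighting and glyph placement vary randomly.
Plants are simple 2-D glyph compositions — stem, leaf-cluster count growing
through the vegetative ordinals, blossom dots for flowering, elongated pods
for podding, a green→brown palette ramp for maturity — and the bounding box
is computed from the rendered mask. Output is deterministic in (spec,
seed): identical bytes on re-generation. Splits use the floor-then-remainder
rule (80/10/10), so 17,204 images give 13,763 / 1,720 / 1,721.

What passing tests on this generator does and does not show: it exercises
every pipeline stage (rendering, COCO I/O, training, matching, denoising,
evaluation, profiling) and the class-conditional structure the method
depends on, but it contains none of the photometric complexity, occlusion,
background clutter or annotation noise of real greenhouse imagery, so
accuracy numbers on synthetic scenes say nothing about accuracy on real
crops.

## Problem sizes used by the checks

The test suite and demonstrations run at deliberately small scales chosen
as this package's own working sizes: the miniature `smoke` preset (tiny
backbone, embed width 32, 12 queries, 64² working resolution) trains on 8
synthetic scenes for 500 iterations and reaches perfect training-set AP,
demonstrating the full learning loop; the smoke training recipe disables
the denoising groups and uses a 2·10⁻³ base rate with late decay —
consistent with the observation that the smallest configurations train
best with the auxiliary components simplified, and because the heavily
perturbed reconstruction queries otherwise dominate the clipped gradient
budget of a tiny model. Full-size variants are exercised for construction,
forward finiteness at reduced resolutions, and analytic profiling at 512².

## Numerical choices and degenerate inputs

* QFL scores are clipped at 10⁻¹² from {0, 1}; GIoU uses an area guard of
  10⁻⁹; group/layer/batch normalization use ε = 10⁻⁵.
* Deformable sampling clamps locations to the feature border and collapses
  the bilinear neighborhood on one-pixel-wide levels; reference points are
  treated as constants inside the attention (gradients reach them through
  the refinement MLPs).
* Ceil-mode downsampling throughout: stage i of an L-pixel input has side
  ⌈L/2^i⌉ for every L, including odd sizes.
* A zero-encoder head degenerates to the embedded identity stack; an image
  with no objects yields an empty denoising batch and a trivially valid
  mask; boxes that degenerate under augmentation are dropped and logged.
* Ordinal label noise clamps (rather than reflects) at VE and R8,
  preserving adjacency semantics at the scale ends.
* The squeeze-excitation bottleneck width rounds up when the channel count
  is not divisible by the reduction ratio.

## Known limitations

Single-plant scenes are the design point; dense canopies with occlusion are
out of scope. The backbone is trained from random initialization here —
checkpoint loading is supported, but no pretrained weights ship with the
package. Batch-norm running statistics make untrained-model inference use
whatever statistics exist at call time (batch statistics before any
training). The CPU implementation is intended for study and verification at
small scales, not production throughput.
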