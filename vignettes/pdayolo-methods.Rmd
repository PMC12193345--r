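---
title: "PDA-YOLO in R: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PDA-YOLO in R: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pdayolo` implements a lightweight one-stage detector for adult stored-grain
insect pests photographed in the collection bottles of monitoring traps,
plus the scaffolding needed to study it without GPUs or the original
(proprietary) image collection: an analytic complexity accountant, a
synthetic scene generator, CPU training, and detection metrics. This
vignette records the model as implemented, the parameters that matter, and
the design decisions taken where the published description left the choice
open.

## The detector

The host network is a YOLO11n-scale backbone / PAN-neck / three-scale
anchor-free head (strides 8, 16, 32; width multiple 0.25, one inner block
per C3k2, C2PSA retained at the deepest stage). Three modifications define
the detector:

1. **PF_C3k2** — every C3k2 keeps its cross-stage topology (1×1 expansion,
   split, inner blocks on one half, concatenation, 1×1 fusion) but its inner
   Bottleneck (routing flag F) becomes a PoolFormer block, and its inner C3k
   (flag T) becomes PF_C3k, a C3k whose Bottlenecks are PoolFormer blocks.
   A PoolFormer block is
   `y = x + (AvgPool3x3(LN(x)) − LN(x))`, then `out = y + MLP(LN(y))`,
   with the MLP two pointwise layers and a GELU between.
2. **DMAE** — a local 3×3 DSConv branch in parallel with edge-aware
   branches at target resolutions `feat_rls = c(3, 6, 9, 12)`: adaptive
   average pooling to r×r, 1×1 channel reduction, 3×3 DSConv, the EFE
   operator `F_out = F_in + σ(DSConv3x3(F_in − AvgPool3x3(F_in)))`, and
   bilinear upsampling back. A weight generator (global average pooling →
   1×1 conv → ReLU → 1×1 conv → sigmoid) produces one scalar weight per
   branch; weighted outputs are concatenated and fused 1×1 back to the
   input channel count.
3. **AIFI** — replaces SPPF: the deepest map is flattened to tokens, a 2D
   sinusoidal positional embedding (temperature 10⁴) is added to queries
   and keys only, 8-head scaled dot-product attention and a two-layer MLP
   run in post-norm order (residual, then channel LayerNorm).

All eight on/off combinations of the three modifications are constructible
via `model_variant()`; substitutions are independent, so their complexity
deltas are additive by construction.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `feat_rls` | 3, 6, 9, 12 | cells | stated branch resolutions of the edge module |
| DMAE `reduction` | 3 | — | channel divisor of the branch 1×1 reduction; calibrated on the complexity budget (below) |
| AIFI `heads` / `hidden` | 8 / 512 | — | head count and MLP width; calibrated on the complexity budget |
| `mlp_expansion` (PoolFormer) | 4 | — | canonical PoolFormer ratio; keeps the PF substitution cheaper than the Bottlenecks it replaces |
| training defaults | 150 epochs, batch 16, lr 0.01, SGD momentum 0.937, weight decay 5e-4, 640×640 | — | the study's hyperparameter table, echoed in every run log |
| NMS | IoU 0.45, conf 0.25 (prediction), conf floor 0.001 (evaluation sweeps) | — | host-framework conventions |

**Complexity calibration.** The accountant counts 2 FLOPs per
multiply-accumulate for convolution and linear layers, with batch-norm
fused into the convolution and parameter-free operations (pooling,
activations, normalisation, attention softmax and its matrix products,
upsampling) uncounted — the convention under which the baseline reproduces
its reported 6.3 G at 640×640. Knobs the published description leaves open
were fixed against the reported per-module deltas (−0.3 G PoolFormer,
+0.3 G AIFI, +0.6 G DMAE): DMAE `reduction = 3` (2 overshoots the DMAE
budget by ~0.1 G, 4 undershoots slightly more than 3), AIFI hidden width
512 (the cited source's 1024 would cost ~+0.5 G). These are architectural
constants of this implementation, not tuning handles.

## Design decisions on open points

* **Pooling divisor.** Both the PoolFormer token mixer and the EFE operator
  use 3×3 stride-1 average pooling whose divisor counts only in-image
  cells. This makes "pooled mean of a constant map = the map" exact at the
  borders, which in turn makes the EFE edge map of a constant input exactly
  zero — the property the module's tests pin down.
* **Token mixer subtraction.** The mixer is `AvgPool(x) − x`, per the
  canonical PoolFormer design the block descends from; the prose describes
  only the pooling, so the subtraction is pinned to that source.
* **Replicate padding inside DMAE.** 3×3 depthwise convolutions in the
  DMAE branches clamp border indices instead of zero-padding. At branch
  resolutions as small as 3×3 almost every cell is a border cell, and zero
  padding would imprint a strong artificial frame; replicate padding also
  makes every DMAE stage map spatially constant inputs to spatially
  constant outputs, a testable invariant. Backbone/neck convolutions keep
  the usual zero padding.
* **Branch weights** are scalars per branch with independent sigmoids (not
  a softmax across branches), because the weighting equations apply each
  weight independently.
* **Upsampling** of branch outputs back to the input resolution is
  bilinear with half-pixel centers; the fusion concat requires a common
  size and the description does not name the operator.
* **DMAE placement**: one channel-preserving module at each of the three
  neck outputs feeding the head. Only "into the neck" is stated; this
  placement matches the complexity budget and leaves the PAN wiring
  untouched. Inside the assembled network, branch resolutions cap at the
  feature-map size so the detector stays valid at small input sizes (at
  640×640 the cap never binds); the standalone branch operator keeps the
  strict contract and rejects r larger than the map.
* **AIFI norm placement** is post-norm (residual, then normalise),
  following the stated order of operations; the positional embedding
  enters queries and keys only, per the design AIFI descends from.
* **PF_C3k wiring**: "replace each Bottleneck inside C3k with a PoolFormer
  block", keeping C3k's three 1×1 convolutions. The original figure shows
  this only graphically; this reading is the assumption implemented.
* **Batch normalisation** is carried in fused form (absorbed into each
  convolution's weights and bias) — the same form the complexity convention
  counts. Training therefore optimises conv+bias directly, which is
  well-behaved at the tiny batch sizes used on CPU.
* **Loss and assigner** are deliberately plain plumbing, not a
  contribution: each ground-truth box is assigned to the cell containing
  its center at every scale; classification is BCE over all cells
  normalised by the positive count; box regression is the two-bin
  distribution-focal cross-entropy over 16 bins per side. Gradients are
  clipped at global norm 5 and the learning rate ramps linearly over the
  first 3 epochs.

## Numerical choices

Parameters initialise He-uniform from R's RNG; `build_model(seed)` makes
initialisation a pure function of the seed (identical checksums). Layer
normalisation uses eps 1e-5. Softmax rows subtract their maximum.
Degenerate metric cases are defined, not NaN: precision/recall/F1 are 0
when their denominators vanish; AP requires at least one ground truth and
classes absent from the truth are skipped and recorded. DFL targets clamp
distances to [0.001, 14.999] bins. Greedy NMS and greedy matching break
ties by order after a decreasing-confidence sort. Every forward pass is
checked against independent loop-based oracles at tolerance 1e-5 or
tighter, and every backward pass against central finite differences.

## The synthetic generator

The generator emulates the imaging scenario, not the images: a bright
bottle-floor disc (physical radius 40 mm at 6 px/mm, frame 1100×1080),
tan elliptical wheat kernels and dark debris specks as clutter, and 1–8
insects per scene drawn as dark oriented ellipses (body + head, lighter
wing shading for the two moth species) whose pixel length is uniform in
each species' body-length range (LGB 2.3–3.0 mm, RFB 2.3–4.4, IMM
8.0–10.0, MW 2.5–4.5, AGM 4.0–6.0). Labels are the minimum axis-aligned
enclosing rectangle of the rendered insect pixels. Everything is a
deterministic function of the seed. A global `scale` factor shrinks frame
and px/mm together; counts, split arithmetic and size *ordering* are
scale-invariant, and rendered bodies never collapse below ~2 px so each
insect always owns a label.

What it does **not** emulate: real insect texture and pose, occlusion by
grain, specular reflections, lighting drift, or inter-class appearance
subtlety. Passing tests therefore demonstrate that the architecture,
optimisation and metrics are implemented correctly — not that the reported
detection accuracy on the proprietary trap dataset would be reproduced.
Accuracy-level claims are out of scope by design (the dataset is not
public and training at full scale is GPU work).

## Problem sizes used by the checks

The package's own verification runs at desk scale: the complexity ledger
at full 640×640 (analytic, seconds); the dataset-arithmetic check at
`scale = 0.1` (counts are resolution-independent); oracle equivalences on
maps of at most 8×8×8; and the training smoke run on 8 scenes at 160×160
for 30 epochs with batch 8 — the full detector, roughly 0.4 GFLOPs per
forward pass, a few minutes on one CPU core. The smoke run asserts that
the loss decreases and that the trained detector fires on its training
scenes; it makes no accuracy claim.

## Known limitations

* Single-image batches internally (gradients accumulate across a batch);
  no batch statistics, data-loader augmentation, EMA, or cosine schedule.
* CPU-only by design; a full 640×640, 150-epoch training run is
  arithmetically correct but not practical here.
* The FLOPs accountant resolves shapes statically and rejects dynamic
  ones.
* mean detection time depends on hardware and BLAS; it is reported but
  never asserted against.
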