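---
title: "A dual-stream frequency-decomposed convolutional classifier: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-stream frequency-decomposed convolutional classifier: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Medical image classifiers must read two kinds of evidence at once: fine,
high-frequency texture (lesion boundaries, speckle, micro-calcifications) and
coarse, low-frequency structure (organ shape, anatomical context). Plain
convolutions see only a local window; self-attention sees everything but at
quadratic cost. This package implements a lightweight convolutional
architecture that splits feature maps into explicit low- and high-frequency
streams, processes them in parallel, and fuses them adaptively — at cost
linear in the number of pixels.

The network is assembled as

```
image → ResNet-18 backbone → f_b (512 × H/32 × W/32)
       → { SpectralFlow (USM) ‖ ContextGate (GM) }  on the same f_b
       → fused = f_b + USM(f_b) + GM(f_b)
       → fused + SpectralFlow₂(fused) → BatchNorm → GAP → linear head
```

### SpectralFlow

Given an input `x` with C channels, the module:

1. reduces `x` to `x_l` (C/r channels, r = 2 by default) with a 1×1
   convolution;
2. average-pools `x` globally, and maps the pooled descriptor through a
   learned 1×1 convolution to one k²-vector of filter logits per reduced
   channel; a softmax over the k² patch positions yields nonnegative weights
   summing to one. Because they derive from the global descriptor, the same
   weights apply at every spatial patch — a dynamic convolution informed by
   the whole image;
3. partitions `x_l` into non-overlapping k×k patches and replaces each patch
   by its weighted mean under those weights, broadcast back to all k²
   positions. The result `x_la` is piecewise constant at patch granularity —
   a genuinely low-frequency map at full resolution;
4. projects `x_la` back to C channels (`x_la_proj`) and defines the
   high-frequency residue `x_h = x − x_la_proj`. This is a definition, not an
   approximation: `x_la_proj + x_h` reconstructs the input exactly, which the
   test suite asserts to machine precision;
5. pools each stream, derives per-channel attention logits with per-stream
   1×1 convolutions, normalizes the pair (softmax across {low, high} per
   channel, so `a_l + a_h = 1`; an independent-sigmoid variant is available),
   and mixes `a_l ⊙ x_la_proj + a_h ⊙ x_h` through a final 1×1 convolution.

Every counted operation is a 1×1 convolution or a patch-wise weighted mean,
so the cost is linear in H·W; the profiler verifies the linearity exactly.

### ContextGate

Three pathways run in parallel on the same input:

* **spatial** — depthwise 3×3 convolution, refinement by an internal
  SpectralFlow at full width, then a 1×1 reduction to m = ⌊C/3⌋ channels;
* **gating** — 1×1 convolution to m channels followed by a GELU (default) or
  sigmoid;
* **identity** — a plain 1×1 projection to m channels.

The spatial and identity outputs are concatenated (2m channels) and
multiplied elementwise by the gate, repeated once along channels so the same
weights modulate both halves. A final 1×1 convolution restores C channels and
the block adds its input back residually. With every learned parameter at
zero the block is exactly the identity map — the property the optimizer
starts from, and one the tests assert bit-for-bit.

## Design choices where the design was open

* **Channel arithmetic.** ⌊C/3⌋ is used for the branch width (512 → 170) and
  the final projection maps 2·170 = 340 → 512; C/3 is not an integer at the
  reference width.
* **Gate width.** The gate has m channels but modulates a 2m concatenation;
  it is repeated once channelwise rather than widened, keeping the printed
  gate shape with the least machinery.
* **Gate range.** The GELU default follows the block's description even
  though GELU is not bounded in [0, 1]; the sigmoid option honors a strict
  (0, 1) gate. Both are config switches.
* **Reduction placement.** The spatial pathway refines at full width and
  reduces last (depthwise C → SpectralFlow C → 1×1 C→m); dropping width
  before refinement would discard information the refinement could still
  use.
* **Non-divisible extents.** When k does not divide H or W (a 7×7 map with
  k = 3, or the 1×1 map of the 32 px configuration), the map is padded
  bottom/right with symmetric (edge-inclusive mirror) padding to the next
  multiple of k and cropped after smoothing. Pure reflection without the
  edge is undefined when the pad exceeds the extent (1×1 → 3×3), so the
  total, edge-inclusive member of the reflection family is used.
* **Second-module residual.** The second SpectralFlow is applied residually,
  `fused + SF₂(fused)`. A non-residual refinement would annihilate the whole
  head at zero initialization (its zero-parameter output is zero), making
  the zero-parameter network degenerate rather than backbone-equivalent;
  the residual keeps the network a perturbation of the backbone at
  initialization, which also stabilizes early training.
* **Fusion.** `f_b + USM(f_b) + GM(f_b)` is taken literally; since the gated
  block carries its own internal residual, the backbone features are counted
  twice in the sum. Batch normalization downstream makes the network
  insensitive to that constant factor.
* **Attention target.** Stream attention is applied to the C-channel
  projected low stream (not the C/r stream), because the two streams are
  summed and must agree in width.
* **Bias initialization.** All 1×1 convolution biases start at zero so that
  zero input maps to zero output and the residual-identity tests are exact.

## Training procedure

Cross-entropy on logits; Adam (default, lr 1e-3), SGD (momentum 0.9) and
RMSprop are available. Two augmentation arms mirror the ablation design:
`"normal"` (random horizontal flip only — the default) and `"cutmix"` (flip,
affine with translation up to 10%, perspective distortion, color jitter,
Gaussian blur, random erasing at probability 0.5, plus batch-level CutMix at
probability 0.5 with Beta(1, 1) mixing). Under CutMix the loss is
`lam·CE(labels_a) + (1−lam)·CE(labels_b)` with `lam` the post-clip box-area
fraction. Augmentation magnitudes (jitter half-ranges 0.2/0.2/0.2/0.02,
blur σ ∈ [0.1, 1], erase area 2–20%) are the common mild settings and are
all exposed in `augmentation_config()`. Evaluation never augments: resize
and normalize only, with batch-norm running statistics. The best parameter
state by evaluation accuracy is restored after training. Every source of
randomness — initialization, shuffling, augmentation draws — derives from
the single run seed.

Learning rate, batch size, weight decay and schedule are free choices here:
Adam 1e-3, no decay, no schedule, and whatever batch size fits the problem
(the package defaults to 32 at desk scale, 128 being the conventional
benchmark value). They are recorded in every checkpoint sidecar.

## The synthetic two-frequency dataset

`synth_generate()` builds grayscale-replicated RGB images in which class
evidence is deliberately split across frequency bands: each class has a
low-frequency radial blob at a class-specific position and scale, plus a
high-frequency sinusoidal grating at a class-specific spatial frequency and
orientation, with per-image center jitter, random grating phase, and
additive Gaussian pixel noise (σ = 0.05 by default). Both SpectralFlow
streams therefore carry class information. The default study condition used
by the learnability check is 4 classes at 32×32: 200 training and 100 test
images (seeds 101 and 202), 30 epochs of Adam at defaults, batch 32 —
chosen as the smallest configuration where a randomly initialized backbone
must genuinely learn both bands, and small enough to rerun routinely on a
single CPU (the full check runs in a few minutes).

What the generator does **not** emulate: modality-specific intensity
statistics, anatomical shape priors, annotation noise, class imbalance, and
acquisition artifacts. Passing the learnability check shows the
architecture, gradients, and training loop work end to end on separable
two-band structure — it says nothing about clinical performance.

## Metrics

Confusion counts follow the standard binary definitions; multiclass accuracy
is trace over total. ROC curves sweep the distinct score values (ties
collapsed into one threshold step) with TPR = TP/(TP+FN) against
FPR = FP/(FP+TN), integrated trapezoidally; the implementation is tested
against an exhaustive concordant-pair (Mann–Whitney) oracle and against an
established reference implementation. PR curves report precision against
recall per threshold and are integrated step-wise (average precision),
avoiding the optimistic bias of linear PR interpolation. Multiclass curves
are one-vs-rest on probability columns; classes absent from the labels are
flagged and excluded from macro averages.

## Profiling convention

`count_macs()` counts one multiply-accumulate per fused multiply-add of
every convolution (`Cout·Cin/groups·k²·Hout·Wout`) and linear layer
(`Cin·Cout`); normalization, activations, pooling, elementwise arithmetic
and the patch-smoothing aggregation count zero. Under this convention the
18-layer residual baseline with a 1000-class head measures 11.7 M parameters
and 1.81 G MACs at 224×224; conventions that also count pooling or
normalization land near 1.82 G and are deliberately not used. The convention
string is embedded in every report. The package reports its own true
parameter count (≈ 18.3 M with the 512-channel backbone and all three
SpectralFlow instances) rather than any smaller figure; its MAC count at
224×224 is ≈ 1.92 G, within the 2.00 G budget, and all added modules run at
1/32 of the input resolution, adding under 10% to the backbone's MACs.

## Numerical notes

* Reverse-mode gradients are hand-derived per operation and validated by
  central finite differences (relative error ≤ 1e-7 at module scale).
* Batch normalization uses ε = 1e-5 and momentum 0.1 with per-channel batch
  statistics; exact scale-cancellation identities therefore hold only up to
  ε.
* GELU is the exact Gaussian form `x·Φ(x)`, so the gate value at a forced
  pre-activation of 1 is Φ(1) = 0.8413447…, used as a unit anchor.
* The pairwise stream softmax is computed as a sigmoid of the logit
  difference, which is exact and avoids overflow.
* Grad-CAM maps flag "low evidence" when the raw rectified map's maximum is
  below 1e-8 and return all zeros rather than amplifying noise through
  min–max normalization.
* Arrays are stored H × W × C × N (spatial-major); convolutions run as
  batched im2col + GEMM in compiled code.

## Known limitations

* CPU-only, double precision; practical for the desk-scale configurations
  above, not for 224 px benchmark training.
* Pretrained backbone weights are not bundled; all shipped configurations
  use seeded random initialization. The checkpoint reader will restore any
  compatible parameter state.
* JPEG image folders are not supported (PNG only).
* The "test accuracy above train accuracy" pattern seen with train-only
  augmentation is reproduced qualitatively by the history curves, not
  asserted numerically.
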