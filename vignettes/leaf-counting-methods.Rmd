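---
title: "Counting rosette leaves from images: models, simulator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting rosette leaves from images: models, simulator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Leaf count is a standard trait in plant phenotyping: it tracks growth
stage and responds to genotype and environment. For rosette plants
(Arabidopsis and relatives, or komatsuna), plants are imaged top-down and
the task is to predict the integer number of leaves per image. Two things
make it hard: leaves overlap each other, and backgrounds (soil, pot rims,
moss, green tints) can resemble leaf tissue.

`lcnet` implements a two-stage pipeline for this task:

1. **Segmentation.** A SegNet-style encoder–decoder predicts a per-pixel
   leaf probability from the RGB image. Encoder stages are stacks of Conv
   Blocks (3×3 convolution without bias → batch normalization → ReLU)
   followed by 2×2 max-pooling that records its argmax indices; decoder
   stages upsample by placing values back at those indices (index
   unpooling) and mirror the encoder's Conv Blocks; a final 1×1
   convolution with a sigmoid produces the probability mask.
2. **Normalization layer.** A threshold filter sets every mask value
   below 0.5 to zero and passes values at or above 0.5 through unchanged.
   This removes spurious low-confidence pixels caused by uneven
   background or reflections. The operation is idempotent, and a
   `binarize` option produces hard \{0,1\} masks for users who want them.
   Values exactly at the threshold are kept (only values *below* the
   threshold are zeroed).
3. **Counting.** The counting network takes the RGB image concatenated
   with its (normalized) mask as a 4-channel input. Each stage applies
   one 1×1 Conv Block at a narrow "bottleneck" width followed by three
   3×3 Conv Blocks at the stage width, then 2×2 max-pooling; the head is
   global average pooling and a single linear unit, trained with the
   smooth L1 (Huber) loss against the integer count. Three stacked 3×3
   convolutions cover at least a 5×5 receptive field while — given the
   preceding bottleneck — spending fewer parameters than a single wide
   5×5 convolution; the test suite asserts this inequality on the default
   width schedule.

The two models are trained independently: the segmenter on binary
cross-entropy against ground-truth masks, the counter on smooth L1
against ground-truth counts, with the mask channel coming either from
ground truth or from the trained segmenter (`mask_source` in
`train_config()`).

At full scale (`preset = "paper"`), the counter uses a 224×224 input and
the width schedule (24,48), (48,96), (96,192), (192,416); its trainable
parameter count is 4,976,625, which `scripts/acceptance.R` recomputes and
reports in millions. The full-scale segmenter preset follows a VGG-style
stage schedule (2,2,3,3,3 convolutions at widths 64,128,256,512,512).
The exact filter configuration behind the original SegNet's published
parameter total is not recoverable from its description, so fidelity here
is to the architecture family rather than a specific parameter count.

## Why a simulator, and what it does (not) emulate

Public rosette benchmarks are external downloads with GPU-scale training
costs. To make every stage of the pipeline trainable and testable
self-contained, `rosette_sim` generates images procedurally:

- a scene is `count` elliptical leaves placed at base angles
  `2*pi*k/count` plus uniform jitter, displaced radially from a central
  point — the radial arrangement that defines a rosette;
- rendering rasterizes leaves in painter's order (later leaves occlude
  earlier ones) over a textured background (`soil`, `pot`, or the
  deliberately hard leaf-tinted `green`), then applies a linear
  illumination ramp and additive Gaussian noise;
- the ground-truth mask is the exact union of rasterized leaf interiors
  (a pixel is inside a leaf iff the rotated-ellipse inequality holds at
  the pixel center), and the count is exact by construction.

Determinism is a contract: image `i` under master seed `s` is generated
from the sub-seed `hash(s, i)`, so datasets reproduce byte-identically
and any single image can be regenerated without replaying the stream.

The simulator reproduces the *structure* of the benchmark regime
(overlapping leaves, radial topology, hostile backgrounds, exact
per-pixel masks) but not its photometric richness: no shadows, specular
highlights, soil debris, leaf venation, petioles, or species-specific
shape variation. Passing the desk-scale experiments therefore shows that
the models and training loop work end-to-end and that the combined input
helps on this family of scenes; it does not certify accuracy on real
benchmark images.

Simulator defaults ("easy" preset): counts 3–8, 64×64 canvas, leaf
length 18–26 px and width 7–11 px, angular jitter 0.12 rad, overlap level
0.15, soil background, illumination amplitude 0.12, noise sigma 0.02.
The "hard" preset raises counts to 3–12, jitter to 0.35, overlap to
0.75, noise to 0.05, and switches to the green background. These were
fixed once as plausible desk-scale analogues of top-down rosette imagery;
leaf sizes are large relative to the canvas so that leaves remain several
pixels wide after downsampling.

## Desk-scale study conditions

The `desk` preset is the configuration every training experiment in the
test suite uses: 350 easy-preset images (200 train / 50 validation / 100
test), segmenter with stages (2,8),(2,16) at 64×64 trained for 8 epochs,
counter with stages (6,12),(12,24),(24,48) trained for 15 epochs on
32×32 bilinearly resized input, Adam at learning rates 1e-3 / 2e-3 with
a 0.97 per-epoch decay, batch size 16, ground-truth mask channels.

Two of these choices deserve justification:

- **The counter consumes 32×32 input** while the dataset canvas is
  64×64. Resizing is already a first-class pipeline step (the full-scale
  regime resizes everything to 224×224), leaves remain ~5–13 px across
  at 32×32, and the receptive-field arithmetic of three stages with
  pooling still covers the whole plant. This makes the whole desk study —
  several seeds of both ablation arms — tractable on one CPU core.
- **The ablation uses ground-truth masks** for the combined arm. The
  point of the ablation is the value of the extra mask channel; sourcing
  masks from a concurrently trained segmenter would confound that with
  segmenter quality. `cmd_train_count()` accepts a segmenter checkpoint
  when the coupled configuration is wanted.

## Numerical choices

- Binary cross-entropy clips probabilities to `[1e-7, 1 - 1e-7]` before
  the logarithm; the training loop backpropagates the fused
  logit-gradient `(p - y)/N`, which is exact and stable.
- Smooth L1 uses `delta = 1` by default (`huber_delta` in
  `train_config()`); the loss is continuous with matching one-sided
  slopes at `|d| = delta`.
- Batch normalization uses biased batch variance, `eps = 1e-5`, and
  running statistics with momentum 0.1; evaluation always uses running
  statistics.
- Weights are He-initialized (fan-in) from a seeded stream, so model
  construction is reproducible; Adam uses the standard
  `beta1 = 0.9, beta2 = 0.999, eps = 1e-8`.
- Max-pooling breaks ties toward the first element scanned
  (deterministic); unpooling writes each value to its recorded argmax
  position and leaves the rest zero.
- Raw count predictions are rounded half away from zero and clamped at
  zero (`round_count()`): a regressor output of 2.5 means "at least
  halfway to 3", and negative predictions are physically impossible.
  Counting metrics are computed on rounded predictions by default, with
  raw-value MSE/R² available alongside (`count_metrics(raw = )`) for
  sensitivity analysis.
- Bilinear resizing evaluates the interpolation formula at target pixel
  centers (`src = (dst + 0.5) * scale - 0.5`, clamped); masks are
  resized by nearest neighbour so they stay strictly binary rather than
  being re-thresholded after interpolation.
- Empty-mask conventions: IoU and Dice are 1 when both masks are empty
  (perfect agreement on "no leaf") and 0 when exactly one is; R² is an
  error, not a silent 0, when the ground truth is constant.

## Open design points, resolved

- **"Vertical flip"** is mirroring about the horizontal axis (row order
  reversed), the common imaging convention; it is one of four closed
  augmentation ops (with ±90° and 180° rotations) whose compositions stay
  inside the square's 8-element dihedral group.
- **Split remainder** goes to train: validation and test sizes are
  `round(n * fraction)` and train absorbs the rest, which reproduces the
  1410/300/300 partition of 2010 images at the corresponding fractions.
  The shuffle is seeded and unstratified.
- **Augmented copies are materialized on disk** rather than generated
  on-the-fly, and by default only the training split is expanded.
- **Whether the normalization layer participates in segmentation
  training:** it does not; it is applied to segmenter outputs at the
  interface to the counter (and in `predict`/`evaluate` paths), matching
  a post-hoc filter reading of the design.
- **Stage count of the counting network:** the architecture's text fixes
  the stage pattern (1×1 bottleneck, triple 3×3, max-pool) but not the
  depth; the full-scale preset uses four stages with the width schedule
  above, chosen so the parameter budget lands on 5M.

## Limitations

- The CNN engine is CPU-only, double-precision, and sized for desk-scale
  experiments; it is not a general deep-learning framework.
- Simulator realism is bounded as described above; conclusions about
  real CVPPP/KOMATSUNA-scale accuracy require real data and full-scale
  training, which are outside this package's scope.
- Instance-level (per-leaf) segmentation metrics are out of scope; the
  segmenter is binary leaf-vs-background.
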