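---
title: "Methods: models, numerics and design choices in osteoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, numerics and design choices in osteoseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The segmentation problem

Micro-CT volumes of mammalian long bones are segmented per voxel into
background (class 0), cortical/trabecular bone (class 1) and medullary
pores (class 2). Bone is the bright, dense shell; pores are void spaces
inside the marrow cavity that image at background intensity and are
distinguishable from exterior background only by context. Marrow itself
belongs to the background class. The classes are strongly imbalanced —
pores are typically on the order of 1% of voxels — which drives several
numerical choices documented below.

# Data handling

**Scan-level splitting.** Adjacent slices of one scan are nearly
identical, so any split that assigns slices independently leaks
information from training into validation and inflates performance
estimates. All partitioning in osteoseg therefore operates on whole
scans: `split_scans()` shuffles scan ids with a seed and takes the first
`clamp(round(N·fraction), 1, N−1)` as training (the count that realizes
the requested fraction as closely as whole scans allow), and
`build_folds()` cuts a fixed, pre-shuffled scan order into k consecutive
equal blocks, each serving once as a test fold with the ordered
complement as the training/validation pool. `fit()` refuses any split in
which a scan id appears on both sides.

**Normalization** (`compute_norm_stats()`, `normalize_patch()`) is
per scan, never per patch: a patch's intensities are mapped with
statistics of its source scan so that within-scan contrast is preserved.
The standard deviation is the population form — it is a normalization
constant, not an inferential estimate. Degenerate scans (zero variance
or zero range) are guarded with ε = 1e-8, mapping to all zeros.

**Augmentation.** One geometric branch is drawn per patch from a single
uniform variate with cumulative thresholds at the literal published
probabilities 0.166 / 0.166 / 0.5 / 0.168 (horizontal flip, vertical
flip, quarter-turn rotation uniform over 90/180/270 degrees, none) —
these sum to exactly 1. Rotations are restricted to quarter turns so the
integer label mask transforms without interpolation. Intensity
augmentation operates on normalized patches: with independent 40%
probabilities a contrast factor (uniform in [0.75, 1.25]) and a
brightness shift (uniform in [−0.15, 0.15]) are drawn *once per batch*
and applied to all scan patches in it (contrast first, then shift — the
order is fixed for reproducibility), after which intensities are clipped
to the dynamic range of the normalization mode ([0, 1] for min-max;
z-score values are unbounded and are not clipped). Masks are never
intensity-augmented. The geometric transform is applied per patch (after
cropping) rather than per tile: patches are square by construction, which
keeps quarter-turn rotations shape-safe for non-square tiles; scan and
mask always receive the identical transform.

**Patch sampling.** Each epoch visits every training tile once in a
reshuffled order; `patches_per_tile` random origins are drawn per tile,
with a pairwise-overlap constraint enforced by rejection sampling
(≤ 200 retries per patch; on exhaustion the last candidate is accepted
with a warning, and the constraint is silently waived when it is
unsatisfiable, e.g. patch = tile). Tiles smaller than the patch are
reflect-padded, which avoids manufacturing spurious background edges.

# The model

`tiny_unet` is a compact, fully convolutional encoder–decoder: two
encoder levels (3×3 conv ×2 each, 2×2 max pooling), a bottleneck, and
two decoder levels (nearest-neighbour 2× upsampling, skip concatenation,
3×3 conv ×2), a 1×1 classification head; 16 base channels by default
(~119k parameters). Every convolution except the head is followed by
batch normalization and ReLU. Forward and backward passes are written
against im2col/GEMM primitives in RcppArmadillo; gradients of every
layer, including batch normalization, are verified against central
finite differences in the test suite.

Batch normalization is not an optional nicety here. Training from random
initialization with a pure Jaccard loss and no normalization layers
collapses the rare pore class: the background and bone logits grow to
|logit| ≈ 30 within one epoch, the softmax saturates, and the gradient
reaching the pore class (which is proportional to the predicted pore
probability) vanishes — pore IoU stays exactly 0 regardless of further
training. With batch normalization the same five-epoch budget reaches
pixel-perfect held-out segmentation of easy phantoms.

The published large architectures (U-Net, UNet++, DeepLabV3+, SegFormer
with ResNet/EfficientNet/MiT backbones) are registered and validated in
`model_spec()` so configurations and checkpoints round-trip, but
building them requires an external pretrained-backbone framework that
this package deliberately does not depend on; `build_model()` reports
this explicitly. ImageNet initialization is likewise recognized but
refused offline.

# The loss and its smoothing

The training objective is one minus the mean over classes of the soft
Jaccard index, pooled over the whole batch per class:

  J_c = (⟨p_c, t_c⟩ + s) / (Σp_c + Σt_c − ⟨p_c, t_c⟩ + s + ε)

with defaults s = 0 and ε = 1e-7, matching the reference
segmentation-loss implementations. The choice of s matters more than it
looks: with s > 0 (e.g. s = 1), a batch that contains *no* voxels of a
class makes (I+s)/(U+s) increase as the predicted probabilities of that
class shrink, i.e. the loss actively rewards silencing the class, with
per-voxel gradients approaching 1/s as the union empties — orders of
magnitude above normal gradient scale. For a class as rare as pores this
is a one-way trap. With s = 0 an absent class contributes a constant to
the loss and exactly zero gradient. The smoothing constant remains a
user parameter for comparability experiments.

# Optimization

Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) with the single-cycle cosine
schedule lr(t) = lr_min + ½(lr0 − lr_min)(1 + cos(πt/E)), stepped per
epoch with lr_min = 0 and lr0 = 0.001 by default. Decoupled
(AdamW-style) weight decay of 1e-4 is applied to convolution weights
only — never to biases or batch-norm parameters — bounding logit growth
as a second line of defence against softmax saturation. Epoch metrics
are micro-aggregated: per-class intersection and union counts accumulate
across all batches and are divided once, which the tests verify equals
the IoU of all batches concatenated. Checkpoints are rewritten whenever
validation mIoU improves; final-epoch weights are kept under a separate
name.

**Reproducibility.** Deterministic mode seeds a single R RNG stream that
drives weight initialization, shuffling, patch origins and augmentation;
all numerics are double-precision CPU code, so a rerun on the same
machine is bitwise identical (logs and weights), which the acceptance
suite asserts. Bitwise identity *across* platforms is not promised —
BLAS builds may differ. Mixed precision is recorded as a flag but has no
effect in this backend.

# Prediction

Each Z slice is normalized with statistics computed on the *input* scan
using the normalization mode stored in checkpoint metadata (an unseen
scan has no stored statistics; scan-specific normalization is the
design's invariant). The slice is covered by square chunks whose origins
advance by `floor(chunk·(1−overlap))` with the final chunk aligned to
the far edge (default overlap 0.25; exposed because the original
exposes chunk size but no overlap). Softmax is applied per chunk and
probabilities are averaged where chunks overlap — a convex combination,
so normalization is preserved; softmax-then-average is the documented
order. Slices smaller than the chunk are reflect-padded and outputs
cropped back. Labels are assigned by argmax with ties breaking to the
lowest class index (background wins ties, consistent with the
conservative low-confidence rule), and voxels whose maximum probability
falls below the confidence threshold (default 0.5) are reassigned to
background. The inference batch size is a pure function of chunk size
and a memory budget, so CPU runs never thrash.

# Evaluation and ranking conventions

Per-class IoU is intersection/union of hard label sets; classes absent
from both masks are an undefined 0/0 and are excluded from the mean
rather than scored 0, so scans without pores are not penalized. The
default mean is over all three classes, with `foreground_only` (bone,
pores) as a flag — the upstream reports do not pin the class set, so
both are offered and every report declares which was used. Dice is
derived exactly as 2·IoU/(1+IoU) and reported half-up at 4 decimals.
Cross-validation summaries convert scan-level mIoU to Dice first and
then average (mean-of-conversions); the alternative order
(conversion-of-means) differs in the 4th decimal and the choice is
declared here once.

Model ranking min-max normalizes seven metrics over exactly the records
supplied (mIoU, batch size and GPU utilization upward; FLOPs,
parameters, VRAM and fitting time downward, i.e. inverted after
scaling), then scores each model by the weighted sum with default
weights (0.85, 0.025 ×6); the sensitivity sweep sets the efficiency
weight to (1 − w)/6. A metric column with max = min carries no
information and is normalized to 1 for all records so it penalizes no
one. Ties break by raw mIoU, then label. Hardware metrics (GPU
utilization, VRAM, time) are user-supplied or probe-filled; the toolkit
never fabricates them.

# The phantom generator

`generate_phantom()` builds a long bone as an elliptical cortical
annulus extruded along Z with a marrow cavity containing randomly placed
spherical pores, at a deliberately reduced scale (default 16×64×64
voxels, 16-bit) so every pipeline stage runs in seconds on one CPU. The
difficulty modes mirror the documented variability of real scan
collections: closely packed bones with narrow background corridors,
composite scans with distinct intensity domains along Z, dim
low-contrast scans, 8-bit quantization, drill holes, growth-plate bands,
and a radial brightness ramp approximating beam hardening. Defaults
were chosen once as a realistic easy case: intensity levels 0.08 /
0.40 / 0.80 of full range (background, marrow, bone), Gaussian noise
σ = 0.02 of range, pore density 8% of the marrow cavity with radii
1–3 px.

What a green phantom test does establish: the training loop can fit and
generalize across scans, chunked inference reconstructs and thresholds
correctly, and the bookkeeping (splits, folds, patch counts, metrics) is
exact. What it does not establish: performance on real micro-CT data —
phantoms lack trabecular microstructure, reconstruction noise
correlation, ring artifacts, partial-volume effects, and anatomical
variability, and the published real-scan mIoU values additionally
require GPU-scale training on the deposited scans.

# Known limitations

- Only the compact U-Net backend is runnable; the four published
  architectures are interface-validated stubs without an available
  framework.
- 2.5D and 3D fitting modes are recognized in metadata but not
  implemented; inference chunking is 2D per slice.
- The TIFF codec covers uncompressed single-sample 8/16-bit integer and
  32-bit float slices (both endiannesses read, little-endian written) —
  compressed, tiled or multi-page TIFF are out of scope.
- Multi-GPU paths, GPU monitors and VRAM probes are replaced by
  user-supplied efficiency records.
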