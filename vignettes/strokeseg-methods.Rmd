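---
title: "Methods: a dilated-dense U-Net with transformer decoder stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dilated-dense U-Net with transformer decoder stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Ischemic stroke lesions in MRI are small, diffuse, and heavily outnumbered
by background tissue, which punishes purely local convolutional models and
purely pixel-wise losses. The architecture implemented here attacks both
sides: **dilated dense blocks** (DDBs) combine a large receptive field
(three 3×3 convolutions with dilation rates 2, 4, 8 — a 29-pixel impulse
support without extra parameters) with DenseNet-style feature reuse (each of
*L* dense layers, BN → ReLU → 3×3 conv → dropout, concatenates *g* "growth"
channels onto the running stack); and **multi-head self-attention** in the
decoder lets every upsampled location attend to the whole slice, which helps
delineate lesions with faint or disconnected boundaries.

The graph is a U-Net: stem → three encoder DDB stages with compressing
transition layers (the third transition forms the bottleneck) → a center DDB
→ three decoder stages (nearest-neighbour ×2 upsampling with a
channel-halving 1×1 conv, encoder skip concatenation, a transformer block,
a DDB) → 1×1 conv head → sigmoid. Inputs are single-channel slices in
[0, 1] with spatial dimensions divisible by 8; odd intermediate shapes are
rejected rather than silently padded so that every shape in the network is
exactly reproducible.

## Design choices in the open corners

The architecture family leaves several compositional details open; the
package pins them as follows, as its own design decisions:

* **Stem**: Conv3×3 (stride 1) → BN → ReLU. All downsampling lives in the
  transition layers.
* **Dilated block**: each of the three dilated convolutions outputs
  `dilated_channels` and is followed by BN and ReLU; same-padding preserves
  resolution.
* **Dense layer order** is pre-activation (BN → ReLU → Conv), with dropout
  (default 0.2) after each dense-layer convolution.
* **Transition**: BN → ReLU → 1×1 conv keeping ⌊θC⌋ channels (θ = 0.5
  default, DenseNet convention) → strided 3×3 conv halving height and width.
* **Upsampling** is nearest-neighbour ×2 followed by a 1×1 convolution that
  halves channels; transposed convolution was deliberately avoided to keep
  the parameter accounting simple and checkerboard-free.
* **Attention placement**: the full transformer block (MHSA + FFN, each with
  residual Add&Norm, post-norm by default with a pre-norm option) follows
  every decoder skip concatenation, rather than a lighter attention gate.
* **Tokenization**: feature maps are cut into non-overlapping patches
  (lossless and exactly invertible); each decoder stage uses the smallest
  power-of-two patch that keeps the token count at or below 2,304 at the
  192×192 working resolution — patches (1, 2, 4) for the three stages. A
  **linear patch embedding** projects each token to a model width equal to
  the stage's channel count before sinusoidal positional encoding, and a
  linear unembedding restores the patch afterwards. This keeps attention
  weight shapes independent of the input resolution (so parameter counts
  are, too) and keeps the high-resolution stage affordable; without it the
  highest stage's raw token width (channels × 16) would dominate the entire
  parameter budget.
* **Scaled dot-product**: attention scores divide by √d_h before the
  softmax, the standard stabilization.
* **He-normal** applies to every conv/linear weight (σ = √(2/m), truncated
  at ±2σ); biases start at zero, BN at γ=1, β=0.

## Width calibration

The published parameter budget — 13,662,913 total, 13,649,473 trainable,
13,440 non-trainable — is published without layer widths. Interpreting
"non-trainable" as the batch-norm running statistics (two per normalized
channel, the convention of the framework the budget's split implies) pins
the summed BN widths at 6,720, a linear constraint on the stem width S, the
dilated width D and the growth g. The trainable count is then an exact
integer function of (S, D, g, d_ff), linear in d_ff. The enumeration in
`scripts/calibrate_widths.R` found exactly three integer solutions; two
require stems of 1,334 and 3,218 channels at full resolution — implausible
and computationally hostile — leaving **S = 224, D = 100, g = 24,
d_ff = 2960** (stage width K = 196, attention width d_model = 294) as the
default, verified against the built model. Two consequences are worth
noting: the feed-forward ratio d_ff/d_model ≈ 10 is larger than the usual
2–4× because it is dictated by the exact budget match, and the default head
count is 3 rather than 4 (heads carry no parameters, and 3 is the largest
count ≤ 4 dividing 294; configurations whose width is not divisible by the
requested head count fall back to the nearest divisor automatically).

## Losses and metrics

The printed forms of the Dice and combined losses in the published
formulation are typographically garbled and the BCE is listed with only its
positive-class term; the package implements the standard, computable forms
they describe: two-term BCE (mean over pixels, probabilities clipped to
[1e-7, 1−1e-7]), soft Dice `1 − (2Σyp + s)/(Σy + Σp + s)` with smoothing
s = 1, the numerically stable sigmoid-BCE on logits, and BCE-Dice as their
unit-weight sum. Mean (not sum) reduction was chosen so losses are
batch-size independent; this is a possible source of effective-learning-rate
differences relative to other implementations. For the *metric*, an
empty-vs-empty prediction scores Dice 1 by convention; the *loss* handles
the same case smoothly through s.

## Preprocessing and augmentation

Volumes load from NIfTI with the axis order normalized to depth-major.
"Blank" end slices are trimmed with an explicit criterion (the published
pipeline quantifies none): a slice is blank when fewer than 2% of its pixels
exceed 1% of the slice maximum, and only leading/trailing blank runs are
removed. Slices are resized to 192×192 (bilinear for images, nearest for
masks so they stay binary) and min-max normalized per slice (a constant
slice maps to zeros). Augmentation expands the dataset by a factor of 3 —
matching the published ~3,900 → ~11,700 growth — with one transform per
copy drawn uniformly from horizontal flip, zoom in [0.9, 1.1], shear up to
10°, and rotation in [0°, 90°]; only the rotation interval is stated in the
published description, the other ranges are conservative choices. The same transform is
applied to image and mask and the mask re-binarized. The 80/20 split
shuffles with a recorded seed and partitions at the slice level, matching a
pipeline that randomizes after augmentation; because augmented copies of one
slice can then land on both sides, validation scores on real data should be
read as optimistic, and subject-level splitting (feeding `split_pairs()`
per-subject lists) is the cleaner protocol when leakage matters.

## Training mechanics

There is no deep-learning framework in the package's dependency set; the
layers implement their own forward and backward passes (the dilated
convolutions via tap-wise GEMM in C++), verified by central-difference
gradient checking through the entire flagship graph to ~1e-5 relative
error. Feature maps are rank-3 (H×W×C); minibatches (default 8, the
published setting) are handled by gradient accumulation, so normalization
statistics during training are computed per sample over the spatial plane —
an instance-flavoured batch norm whose parameter counts and inference
behaviour are identical to the batched formulation. Adam (lr 1e-4 default)
updates in place; training for a fixed epoch count with no early stopping or
schedule, matching the published regimen, though both are exposed as
arguments.

## The phantom generator

`make_phantom()` emulates what the pipeline needs from a scan, not anatomy:
an elliptical "brain" with smooth low-frequency texture over a 0.3
background, blank all-zero slices at both stack ends (default 46 per end on
153 slices, so ~61 informative slices per subject — the proportion that
yields roughly 3,900 kept slices across 64 subjects), and 1–3 ellipsoidal
lesions at +0.4 intensity, Gaussian-blurred and overlaid with noise
(σ = 0.05) so plain thresholding does not solve the task. Everything is
seeded and bit-reproducible. What passing tests on phantoms shows: the
architecture can represent and learn its training data, shapes and counts
propagate exactly, and the pipeline is internally consistent. What it does
not show: segmentation quality on real stroke MRI, which depends on
anatomy, modality contrast and acquisition variability that the phantoms do
not model — the published clinical Dice scores are not reproducible without
the gated challenge data and GPU-scale training, and the package makes no
claim about them.

## Problem sizes used by the test suite

The suite keeps everything at desk scale by choice: gradient checks run on a
16×16 flagship with widths (4, 2, 4); the overfitting check trains a
(8, 4, 8)-width flagship on one 64×64 phantom slice for 400 steps at lr
1e-3; the four-loss smoke runs use 20 such slices for 5 epochs; the exact
counting checks use 64 phantom volumes at 32×32 (slice counts do not depend
on resolution) and 3,900 8×8 pairs for the augmentation ratio. The full-size
default model is built once to verify the published parameter triple, and
runs one 192×192 forward pass.

## Known limitations

2D only; single modality per model; full (not windowed) attention, so token
counts must stay moderate; no pretrained weights; instance-flavoured batch
statistics during training as described above; phantom realism as described
above.
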