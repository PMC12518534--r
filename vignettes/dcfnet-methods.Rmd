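---
title: "DCF-Net: model, design choices and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DCF-Net: model, design choices and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dcfnet` implements DCF-Net, a hybrid CNN-Transformer encoder-decoder for 2D
medical image segmentation. Medical images (CT, MRI, dermoscopy) combine
locally textured anatomy with long-range context: an organ's extent can span
half the field of view while its boundary is defined by a few low-contrast
pixels. The architecture pairs a convolutional encoder, which preserves local
detail, with attention-based decoding along the *channel* dimension, which is
cheap at high resolution (a `d x d` similarity instead of `N x N` over
pixels) and well matched to semantic recalibration.

The forward path for an `H x W` image is:

* **Encoder** — a 7x7 stride-4 convolutional stem, then three stages of three
  CPCA blocks (channel-prior convolutional attention) at scales 1/4, 1/8 and
  1/16, with strided 2x2 convolutions between stages.
* **Bottleneck** — two CASA blocks on the deepest (1/16) features.
* **Decoder** — two stages, each: a patch-expanding layer (channels halve,
  spatial dims double), an SSCF block fusing the upsampled features with the
  same-scale encoder skip, and two CASA blocks.
* **Head** — a 1x1 projection to class logits at 1/4 scale followed by 4x
  bilinear upsampling to the input resolution.

Training minimizes the hybrid objective

$$\mathrm{Loss} = \lambda\, L_{CE} + (1-\lambda)\, L_{Dice},$$

with per-pixel softmax cross-entropy and class-averaged soft Dice. The
bundled profiles use SGD with momentum 0.9, initial learning rate 3.4e-3,
weight decay 1e-4, batch 16 and $\lambda = 0.4$ (multi-organ / cardiac), or
Adam at 1e-4, batch 4 and $\lambda = 0.5$ (binary lesions), with polynomial
learning-rate decay of power 0.9 in both cases.

### CASA: channel-adaptive sparse attention

A CASA block cascades four residual stages on layer-normalized tokens
(channel-first ordering, the default):

$$X_c = X + \mathrm{XCA}(\mathrm{LN}(X)),\quad
  X_c' = X_c + \mathrm{MixFFN}(\mathrm{LN}(X_c)),$$
$$X_s = X_c' + \mathrm{TKSA}(\mathrm{LN}(X_c')),\quad
  X_{out} = X_s + \mathrm{MixFFN}(\mathrm{LN}(X_s)).$$

**XCA** (cross-covariance attention) attends over channels:
$\mathrm{XCA}(Q,K,V) = V\,\mathrm{Softmax}(K^\top Q/\tau)$, with the channel
columns of $Q$ and $K$ l2-normalized first so every entry of the `d x d`
cross-covariance matrix lies in $(-1, 1)$, and a learnable temperature
$\tau$ restoring expressive range.

**TKSA** (top-k sparse attention) computes the channel similarity
$S = (Q^\top K)\odot\tau$ per head, keeps only the $k$ largest entries per
row (ties at the threshold are kept), softmax-normalizes, and applies the
result to $V$. Four branches at $k = \mathrm{round}(f\, C_{head})$ for
$f \in \{1/2,\,2/3,\,3/4,\,4/5\}$ are combined with learnable weights
$\alpha_1..\alpha_4$.

**Mix-FFN** inserts a 3x3 depthwise convolution (on the spatial grid) inside
the feed-forward hidden layer, with an inner skip, layer norm and GELU.

### SSCF: skip-connection fusion

Encoder skip $x_1$ and upsampled decoder features $x_2$ (both `C` channels)
are concatenated to `2C`, refined by a dual-residual SCSA block,

$$x_s = x_{cat} + \gamma_1\,\mathrm{SCSA}(\mathrm{LN}(x_{cat})),\quad
  x_f = x_s + \gamma_2\,\mathrm{LiteFFN}(\mathrm{LN}(x_s)),$$

and compressed back to `C` channels by a depthwise 3x3 followed by a
pointwise convolution. $\gamma_1, \gamma_2$ are learnable channel-wise
scales initialized to 0.01, so at initialization the block is (nearly) the
plain compressed concatenation and the attention path grows in as it proves
useful.

## Design choices at genuinely open points

Several details are not fixed by the architecture's published description;
the package resolves them as follows.

* **Softmax axis in XCA.** The softmax normalizes over the key-channel axis
  of the `d x d` matrix, so each *output* channel's mixture weights over
  input channels sum to one — the convention of the cross-covariance image
  transformer family XCA derives from, and the one that makes the
  normalization invariant testable.
* **Temperatures and branch weights.** One log-parameterized scalar $\tau$
  per head, initialized to 1; the elementwise temperature scaling in TKSA is
  a per-head scalar, not a learned matrix. All $\alpha_i$ start at 1,
  unconstrained. `k` is computed as `max(1, round(f * C_head))`, and
  configurations whose fractions would round to zero channels are rejected.
* **Token layout.** Grids are flattened row-major (within a row, columns
  vary fastest) with channels-last tokens; fixed and documented because
  attention results are permutation-covariant in the token index.
* **Stem and bottleneck.** The stem is a single 7x7 stride-4 convolution
  plus channel layer norm; the bottleneck applies two CASA blocks at 1/16
  scale. Both are schematic-only in the source architecture and are recorded
  here as assumptions.
* **Stage widths.** The per-stage channel widths are unspecified upstream;
  they were fixed once by a grid search (`tools/calibrate.R`) so the
  default model carries 42.04M trainable parameters and 18.37 GFLOPs at
  224 x 224, matching the published budget of 42.02M / 18.47G within 1% and
  5%. The calibrated triple is (160, 304, 744). Because widths need not
  double between stages, the decoder inserts a 1x1 channel-matching
  convolution after patch expansion when the halved width differs from the
  skip width; the patch-expanding layer itself always halves channels and
  doubles both spatial dimensions.
* **Layer-norm axis.** All norms are over channels at each spatial position
  (the transformer convention); the fusion equations do not state an axis.
* **CPCA and SCSA internals.** Both encoder and fusion attention units are
  cited modules whose internals the architecture delegates to their own
  papers. The package mirrors their published structure — CPCA: global-pool
  channel gate (bottleneck MLP, reduction 4), depthwise strip convolutions
  1xk/kx1 for k in {5, 7, 11, 21}, pointwise mixer, residual; SCSA:
  four-group depthwise strips k in {3, 5, 7, 9} forming a sigmoid spatial
  gate, then pooled (7x7) 4-head channel self-attention forming a sigmoid
  channel gate. Each is isolated behind a single constructor
  (`nn_cpca()`, `nn_scsa()`) so a drop-in replacement cannot ripple. The
  channel shuffle sits in the gate branch of SCSA, not on the identity
  path, so the saturated-gate limit returns the input unchanged — a
  property the tests rely on.
* **Lite-FFN expansion.** The lightweight feed-forward uses expansion 2
  (1x1 up, depthwise 3x3, GELU, 1x1 down); no ratio is stated upstream and
  2 keeps the block's "lightweight" role relative to the decoder's
  expansion-4 Mix-FFN.
* **FLOP convention.** One multiply-accumulate counts as one FLOP, the
  convention of the profilers used by the architectures whose budgets the
  model is compared against. Convolutions, linear layers and attention
  matrix products are counted; norms, activations and interpolation are
  not. The budget is reported for a single grayscale 224 x 224 input.
* **Head.** "Linear projection to full resolution" is realized as 1x1
  convolution at 1/4 scale plus 4x bilinear upsampling.

## Numerical choices

* **Dice guard.** The soft Dice adds no smoothing term to the numerator
  (keeping its closed-form values exact to five decimals on non-empty
  classes); a denominator guard of 1e-6 only prevents division by zero for
  empty classes.
* **Cross-entropy clamp.** `log(P)` is clamped at 1e-12, so a zero
  probability at a true class yields a large finite loss. The backward pass
  keeps the unclamped `(P - Y)/N` signal so badly mispredicted pixels still
  train; finite-difference tests therefore probe the smooth region.
* **Empty-class DSC.** Both masks empty gives DSC 1; exactly one empty gives
  0 (the usual multi-organ evaluation convention). Empty boundaries make the
  Hausdorff distance undefined; it is reported as `NA` with a warning.
* **HD95.** The 95th-percentile Hausdorff distance is the maximum of the two
  directed 95th percentiles over boundary-to-boundary Euclidean distances
  (boundary = mask voxel with a background orthogonal neighbour), in voxel
  units by default with an optional physical spacing vector. Per-case
  volume aggregation stacks slices before computing DSC/HD, with a
  per-slice mode for the binary regime.
* **Top-k ties.** The mask keeps every entry `>=` the k-th largest row
  value, so all-equal rows are left unmasked. The selection is treated as
  constant in the backward pass (the gradient of the masked softmax at the
  realized mask), which is the derivative almost everywhere.

## The autodiff tape

No deep-learning framework is part of the package's dependency set; the
networks run on a small reverse-mode automatic differentiation tape
implemented in the package (`R/tape.R`, `R/ops.R`) with compiled
im2col/GEMM convolution kernels (`src/conv.cpp`, with direct fast paths for
depthwise and pointwise convolutions). Tensors are environments holding a
value and an accumulated gradient; operations append nodes to a global tape
while recording is on, and `ad_backward()` replays it in reverse creation
order. Every operator's gradient is validated against central finite
differences in the test suite, as is the assembled network end to end (in a
dense-attention configuration, since top-k selection is only piecewise
smooth).

## The phantom generator

`phantom_spec()` / `generate_phantom()` produce seeded synthetic
image/mask pairs in three regimes mirroring the intended application
domains: `multi_organ` (eight radially deformed elliptical "organs" inside
a body silhouette, 9 classes), `cardiac` (left-ventricle disc, myocardial
ring and right-ventricle crescent, 4 classes) and `lesion` (one large
irregular blob, binary). The difficulty axes are explicit: `contrast`
spaces the class intensity levels, `boundary_softness` Gaussian-blurs the
image (never the mask) to create weak boundaries, `noise_sd` adds Gaussian
noise, and blob radii are modulated by random low-order Fourier terms to
create irregular shapes. Masks are always exact, and identical spec + seed
reproduce a dataset bit for bit.

What the phantoms deliberately do **not** emulate: real anatomical texture
and inter-organ appearance correlation, scanner physics and artifacts,
inter-patient variability, 3D slice continuity, and the extreme class
imbalance of clinical data. Passing the learning tests therefore
demonstrates that the architecture, objective, gradients and optimization
loop are correct and can fit and generalize on controlled data — not that
the model reaches clinical benchmark accuracy, which requires the original
datasets and GPU-scale training.

## Problem sizes used by the test suite

The tests exercise a width-reduced configuration (stage widths 16/32/48)
chosen so the full pipeline runs comfortably on one CPU: the overfitting
check trains on eight 64 x 64 lesion phantoms for 120 optimizer steps
(mean training DSC above 0.95), and the generalization check trains five
seeds on a 200-image 48 x 48 phantom dataset (160 train / 40 validation)
for 120 steps, requiring monotone validation-DSC improvement across the
three evaluation checkpoints in at least four of the five seeds. The
default full-width model is still built and forward-passed at 224 x 224 in
the suite, and its parameter/FLOP budget is verified exactly.

## Known limitations

* CPU-only: a training step on the full-width model at 224 x 224 is far
  slower than on GPU frameworks; the package targets methodological use,
  testing and small-scale experiments, not production training.
* 2D only; volumes are handled slice-wise with per-case metric aggregation.
* No pretrained weights are provided (the architecture is explicitly
  designed to train from scratch).
* The CPCA and SCSA internals are faithful stand-ins for cited modules, not
  ports of any reference implementation.
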