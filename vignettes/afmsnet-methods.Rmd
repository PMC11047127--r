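---
title: "Adaptive attention encoder-decoder networks for 3D lesion segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive attention encoder-decoder networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Volumetric segmentation of brain lesions (gliomas on multi-modal MRI,
post-stroke lesions on T1, acute ischemic lesions on DWI/ADC/FLAIR) is an
extreme class-imbalance problem: lesions typically occupy a few percent of a
`128^3`-voxel volume, and clinically relevant errors concentrate at lesion
boundaries and in small structures. This package implements a family of
attention-augmented 3D encoder-decoder networks for this task, the combined
Dice + categorical focal training loss, an evaluation suite that includes the
average Hausdorff distance, the standard volume preprocessing chain, and a
seeded lesion-phantom generator so the entire stack can be exercised and
tested on the CPU without any clinical data.

All tensors use the axis order `(batch, H, W, D, channel)`; voxel indices are
0-based in coordinate arithmetic, and convolutions use stride 1 with "same"
zero padding, so every block preserves spatial shape (borders therefore see
zero context).

## Encoder blocks

**SAEB** (single adaptive encoder block) is a squeeze-and-excitation channel
attention unit: a 3x3x3 convolution, batch normalization, global average
pooling to a per-channel descriptor `S`, a bottleneck of two 1x1x1
convolutions (reduce by the ratio `r`, ReLU, restore), and a **softmax over
channels** producing attention weights `A_c >= 0`, `sum_c A_c = 1`. These
rescale the batch-normalized map channel-wise before a final ReLU. The
softmax is the deliberate design here (the canonical SE block uses a
sigmoid): attention is a probability distribution over channels, so exciting
one channel necessarily suppresses the others. Tests assert the
distributional property directly.

**DAEB** (dual adaptive encoder block) applies channel and spatial attention
in parallel to the output `T` of a 3x3x3 convolution. The channel branch
pools `T` to a global descriptor, passes it through the same
reduce-ReLU-restore bottleneck, and applies a sigmoid, giving `CA in [0,1]`
per channel. The spatial branch concatenates the channel-wise maximum and
average maps (2 channels), convolves them with a 7x7x7 kernel (the
configurable `spatial_kernel`), and applies a sigmoid, giving `SA in [0,1]`
per voxel. Each map rescales `T` elementwise and the two rescaled tensors are
**added**: fusion by addition keeps the channel count unchanged, which the
decoder contract requires (concatenation would double it). DAEB carries no
batch normalization and no output ReLU; its attention sigmoids provide the
squashing.

**SegPath** refines each skip connection before the decoder consumes it. One
iteration computes `ReLU(BN(conv1x1x1(x))) + ReLU(BN(conv3x3x3(x)))` — a
detail branch and a context branch — and `n` parallel iterations, each with
its own parameters, are accumulated by elementwise addition; `n = 0` is a
plain identity skip. We read the iterations as parallel transforms of the
skip input rather than a chain (each iteration is an enhancement *of the
input*); chaining is a plausible alternative reading, but parallel
accumulation is the one consistent with summing the per-iteration outputs.
The extra additive paths also give gradients a short route around the
encoder, which the gradient-flow test verifies (the loss gradient with
respect to a refined skip input is nonzero).

Default SegPath depths are `4, 3, 2, 1` from the shallowest to the deepest
skip: shallow skips carry low-level features with the largest semantic gap to
the decoder and receive the most refinement, mirroring established
residual-skip-path practice. The refinement is applied to skip connections
only, not at the bottleneck.

## Network assembly

`network_spec()` describes the architecture: `n_stages` encoder blocks (SAEB
or DAEB per `variant`), each followed by 3x3x3 max pooling with stride 2; a
bottleneck block; a decoder stage per encoder stage (2x2x2 transpose
convolution with stride 2, concatenation with the SegPath-refined skip, then
two 3x3x3 conv + BN + ReLU refinements); and a 1x1x1 convolution head with a
voxelwise softmax over `n_classes`. Defaults are 4 stages with widths
16/32/64/128 and a 256-channel bottleneck — small enough to train on a CPU
while matching `128^3` inputs (divisible by `2^4`; indivisible inputs are
rejected with an explicit message). The squeeze-and-excitation reduction
defaults to `r = 4`, so every stage width must be divisible by 4.

Initialization is He-uniform for convolution kernels
(`limit = sqrt(6 / fan_in)`), zeros for biases, `gamma = 1`, `beta = 0` for
batch norm, with all draws taken from a single seeded generator:
`build_network(spec, seed)` is bit-reproducible. Batch normalization uses
batch statistics (biased variance, `eps = 1e-5`) in training mode and
running statistics (momentum 0.9) at inference.

Parameter counting (`count_parameters`) covers every trainable scalar. For
matched specs DAEB always costs more than SAEB on the default width grid: a
DAEB block adds a `7^3 x 2 + 1 = 687`-parameter spatial-attention kernel
while dropping only the `2C` batch-norm parameters of SAEB, so the ordering
holds whenever stage widths stay below ~343 channels.

## Differentiation

No deep-learning framework is used: the 3D convolution, transpose
convolution and max-pooling kernels are compiled C++ and a small
reverse-mode tape in R records each forward pass and back-propagates exact
gradients (batch-norm backward uses the standard batch-statistics
derivation). The loss gradient with respect to the probability map is
closed-form and seeds the tape. Unit tests check the whole composed network
against central finite differences at randomly sampled parameters; agreement
is at the `1e-9` relative level, so training uses exact gradients rather
than approximations.

## Training loss

The loss is the sum of two terms over the one-hot truth `G` and the softmax
probability map `P`:

* weighted soft Dice,
  `1 - (2 sum wc G P + eps) / (sum wc G + sum wc P + eps)` with equal class
  weights by default (the background channel participates like any other
  class) and `eps = 1e-5` guarding the ratio;
* categorical focal, `-sum G log(P) (1 - P)^gamma` with `gamma = 1` by
  default; `gamma = 0` recovers categorical cross-entropy. The focal term is
  a sum over voxels as defined; a voxel-mean variant is available
  (`focal_reduce = "mean"`) for readers who prefer size-independent scales.
  Probabilities are clipped to `[1e-7, 1 - 1e-7]` before logarithms so the
  loss and its gradient stay finite.

Optimization is Adam at learning rate `1e-4` with weight decay `5e-4`
implemented as an explicit L2 penalty `wd * sum(W^2)` added to the loss
(gradient `2 * wd * W`), applied to convolution kernels only — biases and
batch-norm scale/shift are exempt, the usual convention. Batches are whole
volumes (batch size 1), per-volume losses averaged per epoch. The checkpoint
with the lowest validation loss is retained and early stopping uses patience
20 on validation loss; an optional `target_dsc` stops training once the mean
training DSC reaches a target, which keeps capacity checks cheap. No data
augmentation is applied anywhere.

## Evaluation

All metrics binarize probabilities at threshold 0.5, with a tie at exactly
0.5 counted positive (the threshold is inclusive). From pooled voxel
confusion counts we report accuracy, precision, recall, DSC
(`2TP / (2TP + FP + FN)`) and IoU (`TP / (TP + FP + FN)`). When a
denominator vanishes: both masks empty is vacuous agreement (metric 1),
exactly one empty is a total miss (metric 0), and such rows carry a
`degenerate` flag. `mean_iou` is the unweighted mean IoU over foreground
classes, background excluded.

The average Hausdorff distance is the symmetric mean of nearest-neighbour
distances between the two foreground voxel point sets, scaled by voxel
spacing in mm. Point sets default to *all* foreground voxels (matching the
definition of the point set of a segmentation result); a surface-voxel mode
is available. Both-empty returns 0 and one-empty returns the physical grid
diagonal as a penalty, both flagged with a warning. The implementation is
exact (C++ double loop over candidate pairs) and is tested against an
independent R double loop at `1e-9`.

Nested evaluation regions follow the standard BraTS convention by default:
whole tumor = {NCR, ED, ET} = raw labels {1, 2, 4}, tumor core = {NCR, ET} =
{1, 4}, enhancing tumor = {4}. An alternative tumor-core reading
(TC = ED u NCR = {1, 2}) appears in parts of the literature;
`brats_regions(tc_literal = TRUE)` selects it rather than guessing intent.
Aggregation over cases is reported both macro (mean and sd of per-case
metrics) and micro (pooled counts), since published tables rarely say which
was used.

## Preprocessing

The transforms are pure functions on volume records and never invent label
values: central crop (centered half-open window; an odd size difference
drops the extra voxel from the high-index side), trilinear image resampling
with nearest-neighbour labels (to a target spacing or a target shape — both
modes exist because published tables list both voxel sizes and input sizes),
z-score normalization per channel over the nonzero (brain) support (standard
for skull-stripped MRI, robust to background zeros), isotropic Gaussian
smoothing (default sigma 0.5 voxels, truncated at 4 sigma, mirror boundary
so constants are preserved), modality fusion by channel stacking, and
one-hot encoding with sparse raw labels (e.g. BraTS `0,1,2,4`) remapped to
contiguous class indices and mapped back on prediction export. Volumes whose
foreground fraction is below 1% are discarded — *strictly* below: a volume
at exactly the boundary is kept. Train/validation/test splits (default
80-10-10) floor each fraction and give the remainder to training, after a
seeded shuffle. Rigid/affine registration and skull stripping are out of
scope: they are performed by external tools upstream of this package.

## Synthetic phantoms

`generate_phantom()` builds a labeled multi-channel volume from randomly
placed axis-aligned ellipsoids with nested class shells (scale factors
`1, 0.6, 0.35` by default, giving a whole/intermediate/core nesting like
WT/TC/ET), per-(class, channel) mean intensities, and additive Gaussian
noise. Defaults — a `64^3` grid, 1-3 lesions with semi-axes of 4-12 voxels,
contrast step 0.6 against background 1.0, noise sd 0.1 — put the foreground
fraction at a few percent, matching the class imbalance the real datasets
exhibit. Ellipsoids are used deliberately: their analytic volume
`(4/3) pi rx ry rz` supplies an oracle for the realized foreground fraction,
and a fixed centered sphere is checked against an exhaustive lattice count.
Overlapping lesions are resolved by letting later lesions overwrite earlier
labels. Everything is a deterministic function of the spec's seed; dataset
seeds are derived from a master seed so generated datasets are reproducible
file-for-file.

What the phantoms do *not* model: MRI physics, bias fields, partial-volume
effects, anatomical context, or non-ellipsoidal lesion shapes. Passing tests
on phantoms therefore demonstrates the correctness of the machinery (blocks,
gradients, losses, metrics, preprocessing) and the optimizer's capacity to
fit, not clinical segmentation quality on real scans.

## Problem sizes used in tests

Block-level oracle checks run on tensors up to `3^3` voxels and 4 channels
against independent scalar-loop evaluations. Network-level contracts use
`32^3` inputs with 2-stage, 4-channel miniature networks. The capacity check
trains such a miniature network on a single normalized `32^3` phantom with
one ~8-voxel lesion (Adam, lr `1e-4`, weight decay `5e-4`) until the
training DSC reaches 0.9, which takes a few hundred epochs (a couple of
minutes on one CPU); these sizes were chosen so the whole suite, including
that run, completes comfortably on one CPU. The acceptance script repeats the capacity run with seeds derived from
its `--seed` argument and additionally reports parameter counts and the
phantom pipeline quantities.

## Known limitations

* Batches are whole volumes; there is no patch sampling, so memory scales
  with volume size.
* Training on realistic dataset sizes is CPU-bound and slow by design; the
  package's purpose is a correct, fully testable reference implementation,
  not GPU-scale throughput.
* Batch statistics with batch size 1 reduce to per-volume spatial
  statistics; running statistics accumulate across steps with momentum 0.9.
* Checkpoint end-to-end determinism holds on a fixed platform/BLAS; across
  platforms, floating-point reduction order may differ at the last ulp.
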