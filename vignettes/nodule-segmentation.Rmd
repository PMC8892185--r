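---
title: "Methods: nested residual 3D segmentation and its comparison pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested residual 3D segmentation and its comparison pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modeling and numerical choices behind
`noduleseg`: what each component computes, which parameters matter and
why their defaults are what they are, what the synthetic phantoms do and
do not emulate, and the known limitations.

## Problem setting

Segmentation of lung nodules on CT is the step that turns a detected
nodule into a voxel mask from which diagnostic features (volume, margin
irregularity, density histogram) are computed. Two morphologies defeat
intensity-driven methods: ground-glass (GGO) nodules, whose attenuation
stays far below solid tissue and whose margins fade gradually into lung
parenchyma, and wall-attached nodules, which are contiguous with chest
wall tissue of essentially the same intensity. All methods in this
package operate on a fixed volume of interest (VOI) of 128 x 128 x 64
voxels centered on the nodule, with axis order (x, y, z), z the slice
axis, and 0-based voxel coordinates in every user-facing argument.

## The nested residual network

The primary segmenter couples three ideas:

1. **Nested decoding.** A single encoder (`e1..e5`, five resolution
   levels, 2x2x2 max pooling between levels) feeds a triangular grid of
   decoder nodes: the node at level i, stage s concatenates all previous
   same-level features with a 2x2x2 transposed-convolution upsampling of
   the level-(i+1), stage-(s-1) node. Four output heads `o1..o4` sit at
   the ends of the decoder chains of depth 2..5.
2. **Deep supervision.** All four heads produce full-resolution
   probability maps and all four enter the training loss. Shallow
   encoder blocks therefore receive a direct gradient signal instead of
   one attenuated through the full depth; the heads are weighted
   uniformly (1/4 each) by default because nothing in the architecture
   argues for an asymmetry. Inference uses `o4` alone — the deepest
   chain sees the most context — binarized strictly at probability
   > 0.5, so an exactly-0.5 map yields an empty mask.
3. **Residual units.** Every block computes H(x) = F(x) + x in
   pre-activation form: F = norm → ReLU → conv(3³) → norm → ReLU →
   [spatial dropout] → conv(3³), with a 1x1x1 projection on the skip
   path only when widths differ. The pre-activation ordering makes the
   unit an exact identity when F's weights vanish, which is also how the
   test suite pins the algebra down bit-for-bit.

Channel widths double per level (`base_width * 2^level`); the reference
configuration is 32/64/128/256/512 and the desk-scale test configuration
4/8/16/32/64. Spatial dropout (whole channels, rate 0.2) precedes each
block's final convolution except in `e1`, where the input statistics are
too impoverished for dropout to help.

**Normalization.** Blocks use per-sample, per-channel (instance)
normalization rather than batch normalization. With volumetric batches of
one or two samples, batch statistics are extremely noisy, and eval-time
running averages would make inference depend on training history;
instance normalization is batch-size independent and keeps inference
exactly deterministic, which the determinism contracts in the test suite
rely on. The statistics are computed over a channel's voxels with
epsilon 1e-5 inside the square root. A corollary worth knowing: at a
spatial size of a single voxel a channel is constant, its normalized
value is exactly the learned offset, and with zero-initialized offsets
deep decoder paths start inactive. Input shapes whose deepest level
collapses to 1x1x1 (e.g. 16³ at depth 5) are therefore legal but start
with dead deepest chains; the default test shape 32x32x16 keeps a 2x2x1
bottleneck and avoids the issue.

## Baselines

*3D U-Net*: same encoder skeleton with plain double-convolution blocks,
transposed-convolution upsampling and one skip concatenation per
resolution; a single output head. *3D SegNet*: encoder records the
argmax of every pooling step; the decoder restores resolution by index
unpooling (values placed back at the recorded positions, zeros
elsewhere) and has no skip concatenations; trained with plain
cross-entropy. The distinction — transposed convolution plus skips
versus unpooling without skips — is the defining difference between the
two baselines, so the implementation keeps it strict.

## Loss

`loss(x, y) = lambda * BCE(x, y) + (1 - lambda) * DiceLoss(x, y)`,
lambda in [0, 1]. BCE is averaged over voxels with probabilities clipped
at 1e-7 (the gradient is zeroed in the clipped range). The Dice loss is
soft — no thresholding of x — with smoothing epsilon 1.0 added to
numerator and denominator so that empty-target batches stay finite and
gradients stay bounded; with binary predictions and epsilon 0 it equals
one minus the Dice coefficient exactly. The two terms pull in opposite
directions at the extremes (pure BCE over-extracts, pure Dice
under-extracts and trains less stably), so the coefficient is worth
tuning: `tune_lambda()` offers a deterministic grid and a small
tree-structured Parzen estimator (uniform startup draws, top-quartile
"good" mixture, candidates scored by good/bad density ratio, fixed
kernel floor 0.1), both reproducible from a seed. The objective is mean
validation Dice of the trained model; the package does not prescribe an
optimal lambda — it depends on the data — and defaults to 0.5.

## Classical methods

**Watershed** (two steps). Step 1 thresholds the volume (fixed HU-like
value or Otsu on a 256-bin histogram) and removes connected components
touching the VOI faces; this excludes the chest wall but, by the same
stroke, any nodule merged with it — the wall-attached failure mode of
watershed is structural, not an implementation accident. Step 2 computes
the exact Euclidean distance transform inside the remaining rough
region, takes its local maxima as marker candidates, thins them greedily
(strongest first) to a minimum spacing `marker_min_distance` (default 5
voxels ≈ the smallest nodule radius of interest), and floods the negated
distance map from the markers with a priority queue, which splits
touching quasi-convex structures at their constriction. The returned
region is the one containing (or whose marker is nearest to) the VOI
center, since the VOI is centered on the nodule; a `largest` rule is
available. Ties in the flood are broken first-in-first-out, making the
output deterministic.

**Graph cut.** The labeling energy is
`E(L) = Region(L) + Boundary(L)`: per-voxel negative log Gaussian
likelihoods of intensity under the assigned label (means `fg_mean` /
`bg_mean`, common sd `sigma_region`), plus, for every neighboring pair
with differing labels, the contrast weight
`boundary_weight * exp(-(I_i - I_j)^2 / (2 sigma_boundary^2))`, scaled
by inverse distance for diagonal neighbors. Gaussian likelihoods and the
exponential contrast term are the canonical grayscale instantiation of
this energy. Region costs are shifted per voxel so their pointwise
minimum is zero — a constant offset that leaves the minimizer unchanged
but keeps all graph capacities nonnegative. The energy is minimized
exactly by reduction to an s-t minimum cut (terminal links carry the
shifted region costs, neighbor links the boundary weights; hard seeds
get effectively infinite terminal capacities), solved with a max-flow
routine; the tests verify global optimality by exhaustive enumeration on
small volumes. Default neighborhood is 6-connectivity: with anisotropic
slice spacing, diagonal weights are geometrically ambiguous, so
26-connectivity is opt-in with 1/distance scaling.

## Phantoms

The generator replaces clinical data with parametric scenes on an
HU-like scale: aerated lung -800, solid nodule +20, GGO nodule -500,
chest wall +40, vessel +30 — values chosen to reproduce the contrast
*ordering* of real chest CT, not calibrated statistics. Geometry is
deliberately minimal: spheres, a planar wall slab on one VOI face
(nodule translated to touch it), a cylindrical vessel of radius 2.5
voxels attached to the nodule. The ideal scene is blurred with an
isotropic Gaussian (the stand-in for partial-volume blur, and the
mechanism producing faint GGO margins) and corrupted with additive
Gaussian noise; the ground-truth mask is the pre-blur, noise-free nodule
support, so it is invariant to blur sigma, noise sigma and seed.
Benchmark sets draw radius (default 8-16 voxels at full VOI scale), blur
(0.5-1.5 voxels) and noise sd (10-30) uniformly; each case carries a
seed derived deterministically from the master seed.

What the phantoms do **not** emulate — lobulated and spiculated shapes,
correlated reconstruction noise, intensity inhomogeneity, respiratory
motion — bounds what green tests mean: they certify the machinery
(losses, gradients, optimizers, energies, transforms, bookkeeping) and
the relative behavior of methods on controlled morphologies, not
clinical-grade accuracy on patient data.

## Augmentation

One case expands to exactly 96 variants: 24 in-plane rotations in 15°
steps about the z axis through the VOI center, crossed with an optional
in-plane mirror and an optional z mirror. This 24 x 2 x 2 decomposition
is the unique one reaching 96 distinct geometric maps: treating x- and
y-mirrors as independent factors double-counts, because mirror-x
composed with mirror-y *is* the 180° rotation. Rotations by multiples of
90° on square slices are exact index permutations; other angles resample
with bilinear interpolation for intensities and nearest-neighbour for
masks (keeping them binary), filling from outside the frame with the
background value. The pipeline order is fixed as crop → normalize →
augment, so interpolation always happens on normalized intensities.

## Training and evaluation protocol

Adam (lr 1e-3, beta 0.9/0.999) on mini-batches of 2 at desk scale, each
sampled volume receiving a random one of the 96 augmentation ops;
augmentation is applied only to training members of a fold, so no
augmented variant of a case can leak into the fold where the case is
tested. DS and IoU are computed per held-out case and aggregated as mean
and sample SD over cases (a flag-free design choice: aggregation over
folds instead of cases can be had by summarizing per-fold record
subsets). Both metrics define empty-vs-empty as 1 (perfect agreement on
absence); an empty segmentation against a nonempty reference is 0
straight from the formula. Methods are compared with a two-sided
Wilcoxon signed-rank test on per-case values — a nonparametric choice
because bounded overlap scores are far from normal — with exact p-values
when the sample is small and untied, and no multiple-testing adjustment.

## Problem sizes

The reference configuration (128x128x64, widths 32..512) is expressible
but deliberately not exercised by the tests; the package's test and
benchmark scale is 32x32x16 with base width 4 (networks) — chosen so a
complete training run is a matter of minutes on one CPU core — with 200
Adam steps for the single-case overfit check and an 80-step holdout run
on a 20-phantom solid benchmark. The graph-cut optimality check
enumerates all labelings of volumes up to 3x3x2; the metric identity
DS = 2·IoU/(1+IoU) is checked exhaustively over all mask pairs on a
3x3x1 grid.

## Known limitations

* The differentiation engine is minimal by design: no GPU, no
  mixed precision, single-sample graph construction per step; wall-clock
  comparisons between the three networks are not meaningful benchmarks
  of the published architectures' speed.
* Instance normalization departs from the batch-norm convention of
  ResNet-style blocks (see above for why); at 1-voxel bottlenecks it
  degenerates gracefully but uninformatively.
* Phantom realism is limited as described; watershed and graph cut
  defaults (thresholds, Gaussian means) are expressed on the phantom
  intensity scale and need re-tuning for real HU data.
* NIfTI I/O preserves the voxel grid bit-exactly and spacing to float
  tolerance; arbitrary affine orientations are not round-tripped, only
  the offset is carried on a best-effort basis.
* Resampling between slice spacings and DICOM assembly are out of
  scope; inputs are assumed already on a voxel grid.
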