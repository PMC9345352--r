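---
title: "Two-stage volumetric segmentation and score regression: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage volumetric segmentation and score regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Structural T1-weighted MRI carries morphological information about brain
structures whose size and shape correlate with cognitive measures such as
fluid intelligence. `segscore` implements a two-stage pipeline for
predicting a continuous per-subject score from a 3D intensity volume:

1. **Segmentation.** An encoder-decoder convolutional network labels 14
   regions of interest (ROIs) drawn from the SRI24 labeling — three
   inferior-frontal-gyrus pairs (codes 11/12, 13/14, 15/16), hippocampus
   (37/38), amygdala (41/42), caudate nucleus (71/72) and thalamus (77/78).
2. **Regression.** Each segmented anatomical family is normalized to a
   fixed-size cube by a two-interpolation "minimum bounding cube" (MBC)
   scheme, and a small volumetric CNN maps the five cubes to the scalar
   score, trained with mean squared error.

The package also ships a synthetic symmetric-phantom generator so every
stage is testable end to end without access to restricted imaging data.

# The symmetry merge

The two hemispheres are roughly mirror images, so the left and right
instances of an anatomical family are given one segmentation class
(`mergeSymmetric`, 5 foreground classes + background). The alternative
one-class-per-ROI labeling (`perRoiClasses`, 14 foreground classes) is kept
as a contrast: with mirrored anatomy the network has to tell left from
right purely from lateral context, which makes the per-ROI task strictly
harder — the package's evaluation harness reproduces that qualitative
ordering on phantoms. Class indices are assigned deterministically by the
family's smallest atlas code (frontal gyrus = 1, hippocampus = 2,
amygdala = 3, caudate nucleus = 4, thalamus = 5); background is class 0 and
participates in the softmax, so the network has 6 outputs in symmetric mode
and 15 in per-ROI mode.

# The segmentation network

The network is a four-level 3D U-Net variant (`segNetConfig`,
`buildSegNet`) built from two units:

* **Recombination block** — a residual unit: 1x1x1 expansion from C to
  `expansion * C` channels, 3x3x3 convolution with batch normalization, a
  ReLU, the attention block below, a 1x1x1 reduction to C', all added to a
  1x1x1 shortcut projection of the input. The ReLU between batch norm and
  attention follows the standard conv-BN-ReLU ordering. With all
  residual-path weights zero the block is exactly the shortcut projection,
  and gradients always reach the input through the shortcut.
* **SegS-E attention block** — a squeeze-and-excitation-style unit: a
  depthwise 3x3x3 convolution with dilation rate 2 (one kernel per
  channel) produces U; a 1x1x1 channel-mixing convolution of U produces a
  voxelwise weight map W with C channels; the output is the Hadamard
  product W * X. The literal form has no squashing nonlinearity (a linear
  gate); `seGate = "sigmoid"` is available as an option. The depthwise
  reading of the dilated step is the only one consistent with computing
  the convolution "over each channel"; a summation bound of c/2 that would
  mix half the channels into each output is recorded as an alternative
  reading but not implemented.

The encoder applies a 1x1x1 stem (16 channels at full resolution by
default), a recombination block per level (default schedule 32, 64, 96,
128), and 2x max pooling between levels. The decoder mirrors this with 2x
transposed convolutions (nearest-neighbor upsampling plus projection is
available behind `upsample = "nearest"`). Skip connections are additive
after a 1x1x1 projection at every resolution — the bottleneck skip is
described as element-wise addition, and using the same form everywhere
keeps the architecture uniform. The extra bottleneck skip takes the tensor
entering the deepest encoder level (64 channels at quarter resolution for
the default schedule), projects it to 96 channels with a 1x1x1
convolution, and adds it to the matching decoder tensor. A 1x1x1 head and
voxelwise softmax produce class probabilities. `segNetShapeTrace` computes
the full static shape trace of any configuration without allocating
tensors.

## Loss and training

Training minimizes a multi-class soft Dice loss,
`1 - mean_k (2 * sum(p_k t_k) + eps) / (sum(p_k) + sum(t_k) + eps)` with
`eps = 1e-5`. The reported metric (`diceLoss`) averages foreground classes
only; the training gradient additionally includes the background class's
term (`includeBackground = TRUE` inside `trainSegNet`), which conditions
early optimization far better when foreground occupies a few percent of a
patch — with foreground-only gradients the optimizer spends hundreds of
steps leaving the uniform-probability plateau. Classes absent from both a
patch and its prediction contribute a Dice of 1 (zero loss), so patches
missing classes train cleanly.

Patches are cubes drawn with uniform origins from the training volumes
(112^3 with batch 10 and 200 iterations per epoch at full scale). Patch
sampling is unconditioned on labels by default; a `requireForeground` flag
redraws until a patch holds at least one foreground voxel, and the
desk-scale protocols below enable it because at small grids a noticeable
fraction of uniform patches is pure background. Optimization is Adam
(default 1e-3; the desk-scale protocol uses a piecewise 3e-3 to 1e-3
decay). Intensities are z-scored per volume over positive voxels before
training. Batch normalization uses per-sample statistics with running
averages for evaluation — the training loop processes patches singly and
averages gradients, so batch statistics in the usual sense do not exist.

Whole-volume inference tiles the volume with windows of the training patch
size at 50% overlap, averages class probabilities across overlapping
windows, and takes the voxelwise argmax. Overlap averaging matters
because window-boundary predictions are noticeably noisier than window
centers; disjoint tiling is available (overlap 0) where speed matters
more than boundary quality.

The 3x3x3 convolutions run their inner matrix products in single
precision by default (parameters, accumulation and everything else stay
double); `options(segscore.fp32 = FALSE)` switches to fully double
precision, which the gradient-check tests use.

# Minimum bounding cubes

For each family (the union of both hemispheres, and of all three
frontal-gyrus pairs — five cubes per subject, matching the regressor's
five inputs), the tightest axis-aligned box is found
(`minimumBoundingBox`), cropped, resampled to `L_max^3` where `L_max` is
the longest box edge, and resampled again to the target edge (64 at full
scale) — `extractMBC`. The single-interpolation baseline (`resizeDirect`)
goes straight from the crop to the target and coincides with the MBC
exactly when the box is already cubic. Resampling is separable
align-corners trilinear for real content and nearest-neighbor for binary
masks; axes being shrunk are prefiltered with a normalized Gaussian of sd
`(inEdge/outEdge - 1) / 2` (the one deliberate deviation from naive
interpolation, to avoid aliasing). Cube content defaults to the intensity
crop masked to the ROI (background zeroed), carrying both morphology and
signal; raw-intensity and binary variants sit behind the `content`
argument.

# The regressor



`buildRegressor` constructs: three same-padded 3x3x3 convolution + batch
norm + ReLU stages with 10, 20 and 1 channels; a flatten (262,144 features
for a 64^3 input); fully connected layers 262,144 -> 4096 -> 64 with
dropout 0.5 between them; and a final linear unit to one scalar (the
output head is implied by the task). The five family cubes enter as the
five channels of one tensor. Training minimizes MSE with Adam on targets centered at the training
mean (the output bias would otherwise crawl toward the score mean at
Adam-step speed); the mean is added back at prediction. Optionally it
holds out a validation fraction for early stopping and keeps the
best-validation weights, applies decoupled weight decay, and augments
each presentation by random axis reflections (with a matching
flip-averaged prediction mode) — appropriate when the target is invariant
to reflections, as it is for bilaterally mirrored anatomy. Evaluation
always runs in eval mode (dropout off, running batch statistics). Note the full-size first FC layer holds about 10^9 weights —
desk-scale work uses a reduced input edge (16) and hidden widths (256,
32), which preserves every architectural element at tractable cost.

# Evaluation

`diceCoefficient` is exact set overlap `2|A n B| / (|A| + |B|)`.
`averageSurfaceDistance` extracts surface voxels — mask voxels with at
least one six-connected background neighbor, the array border counting as
background — and returns the directed mean over surface(A) of minimum
Euclidean distances in mm; a symmetric variant averages both directions.
Six-connectivity is a fixed documented choice; the test-suite oracle
shares the surface definition but computes distances by an independent
O(|A||B|) double loop. Both masks empty is treated as undefined (error)
for the Dice, and ASD requires two nonempty masks.

`resampledEval` repeats a full train/test cycle over seeded resamples
(5 at full scale) and reports mean, sd, and a normal-approximation 95%
confidence interval `mean +/- 1.96 sd / sqrt(n)` — with five resamples any
CI is approximate, and the normal form matches the "mean and 95%
confidence interval" reporting convention. An optional second runner is
compared metric-by-metric with a two-sided Mann-Whitney rank-sum test.

# The phantom

`phantomSpec`/`generateSubject` render a skull-stripped-T1-like volume: an
ellipsoidal brain envelope (intensity 0.35) and 14 mirrored ellipsoidal
ROIs whose left instances sit at fixed fractional positions and whose
right instances are exact mirror images before jitter. Family intensity
means (0.55, 0.70, 0.85, 1.00, 1.15) are spaced three noise standard
deviations apart (`noiseSd = 0.05`), so families are separable in
principle but single-voxel classification is noise-limited — a voxelwise
classifier plateaus well below the network, which must learn spatial
smoothing to pass. Per subject, each family draws a shared scale factor
(uniform within 15%), each side a small extra scale (3%) and translation
(1.5 voxels); translation and per-side scale break mirror symmetry, and
the mirror-Dice of the label map decreases monotonically in expectation as
jitter grows. The score is a linear function of the five family volumes
(normalized to per-mille of the grid so the model is grid-size invariant)
plus Gaussian noise, `sigma = 2` by default against a deterministic score
sd of roughly 4-5: ellipsoids keep the true volumes analytic, and the
score depends only on ROI morphology by construction, so the
cube-to-score information pathway is recoverable in principle.

What the phantom does **not** emulate: anatomical shape, partial-volume
effects, bias fields, scanner artifacts, registration error, or any
nonlinear score physiology. Passing phantom tests therefore demonstrates
that the implementation learns and measures what it claims on data obeying
its own assumptions — not that the pipeline reaches any particular
accuracy on real MRI.

# Desk-scale experiment design

The full-scale protocol (240^3 volumes cropped to 224^3, 112^3 patches,
batch 10, 200 iterations per epoch, five resamplings) is far beyond a
single CPU, so the package's experiments and `scripts/acceptance.R` use
reduced problem sizes chosen once as the package's own desk-scale
conditions:

* **Segmentation recovery:** a 12-subject cohort on a 64^3 grid, 32^3
  patches, a reduced network (stem 4; schedule 8, 16, 24, 32;
  expansion 1), 1200 Adam steps with piecewise LR decay, foreground-aware
  patch sampling, 9/3 train/test split, 50%-overlap inference. This
  reliably reaches mean held-out Dice above 0.8 and directed ASD below 2
  voxels on the phantom.
* **Symmetric vs per-ROI contrast:** five seeds of short paired runs
  (identical cohort, budget and hyperparameters; only the labeling scheme
  and head width differ). Short runs suffice because the ordering — the
  6-class task scores higher than the 15-class task — is driven by the
  left/right ambiguity of mirrored anatomy, not by full convergence.
* **Regression recovery:** 60 subjects on the generator's default 96^3
  grid, ground-truth labels, 32^3 cubes, a reduced regressor (conv 2/4/1;
  FC 32768/64/16; dropout 0.3), 40 fixed epochs on all training subjects
  (no early stopping: a validation split of a 45-subject training set is
  too noisy to stop on), flip augmentation during training and
  flip-averaged prediction. The held-out MSE beats the mean-predictor
  baseline.

  An important property of the cube representation surfaces here: the
  bounding-cube normalization deliberately removes absolute scale, so the
  only ruler left in a family cube is the fixed inter-hemispheric
  separation, and the integer-voxel bounding box plus the per-side
  translation jitter add irreducible noise to that ruler. A linear probe
  on oracle global cube features (per-channel fill fractions and means —
  a strictly easier estimation problem than the CNN's) shows the signal
  is largely present in the large-sample limit but that fitting it from
  45 training subjects is estimation-bound: the probe itself does not
  reliably reach the 3-sigma^2 score-noise band, and neither does the
  CNN, which beats the mean predictor but plateaus above that band.
  Recovering absolute-volume scores through scale-normalizing cubes at
  n = 60 is limited by small-sample estimation error rather than by the
  implementation; larger cohorts or score models that depend on the
  shape information the cubes preserve would relax it.

# Numerical choices and degenerate inputs

* Dice smoothing `eps = 1e-5`; identical one-hot prediction and target
  give loss 0 to within eps, and a class absent from both sides
  contributes zero loss.
* Centered crops put the extra voxel of an odd margin on the high-index
  side; pooling requires even spatial dims and the forward pass rejects
  inputs not divisible by `2^(levels-1)`.
* Same-size resampling is the identity; constants are preserved exactly;
  trilinear output is bounded by the input range.
* Empty ROI, unknown atlas code, two empty Dice masks, and non-3D NIfTI
  inputs raise errors rather than returning conventions.
* Max-pool gradient ties route to the first of the eight pooled positions
  in a fixed scan order.
* Multi-class soft-Dice training occasionally lets one small class
  collapse (never predicted) at an unlucky initialization — the caudate
  nucleus, squeezed between its intensity neighbors, is the usual victim
  on phantoms. `trainSegNet(restartOnCollapse = TRUE)` checks a training
  volume after training and retrains once from a shifted initialization
  seed when a foreground class is absent; the desk-scale protocols enable
  it.
* All randomness (phantom, patch origins, splits, dropout, init) is
  seeded; every experiment records its seeds.

# Known limitations

* The networks are trained on CPU at reduced scale; no claim is made about
  full-resolution accuracy or about real MRI.
* Batch normalization with per-sample statistics differs from large-batch
  batch norm; at these batch sizes it is the honest equivalent.
* The mean-squared-error regressor ignores score heteroscedasticity.
* The resampled confidence intervals rely on a normal approximation at
  n = 5.
* Inference tiling mitigates but does not remove window-boundary effects.
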