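---
title: "Methods: semi-supervised lesion segmentation and importance-driven volume rendering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-supervised lesion segmentation and importance-driven volume rendering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Meningiomas and their surrounding T2/FLAIR hyperintensity (SNFH) occupy a
small fraction of a brain MRI volume, and their intensity ranges overlap
those of healthy tissue. Two consequences drive this package's design.
First, a purely intensity-based transfer function cannot isolate the lesion
in a direct volume rendering, so the renderer consumes *non-scalar* voxels
— a 2-vector of (intensity, mask value) — where the mask comes from an
automatic segmentation. Second, training a segmentation network with random
crops wastes most patches on lesion-free anatomy, so the training pipeline
biases its crop sampling toward slabs that actually contain lesion voxels.

The package implements the whole desk-scale pipeline: phantom generation,
semi-supervised training of a pyramid segmentation network, sliding-window
inference with Dice/HD95 evaluation, and a physically based Monte Carlo
volume renderer with an importance transfer function.

# Segmentation model

## Architecture

The network (`pyramid_net_config()`, `init_pyramid_net()`) is a V-Net-style
encoder/decoder: five encoder stages of one Conv3D(3x3x3) + BatchNorm +
ReLU block each, 2x2x2 max pooling between stages, channel widths
`base_filters * (1, 2, 4, 8, 16)`, and four decoder stages of trilinear
upsampling + skip concatenation + one conv block. Deep supervision heads
(1x1x1 convolutions) sit on the S = 4 decoder resolutions; lower-resolution
heads are upsampled trilinearly to full patch resolution so every head
predicts a per-voxel class distribution over {background, tumor, SNFH}.
A `depth_multiplier` knob stacks extra conv blocks per stage for users who
want something closer to a full residual V-Net stage; the default (1)
follows the single-block layout. Decoder conv blocks use BatchNorm + ReLU
like the encoder; this is an implementation choice the printed layer table
leaves open.

Because no deep-learning framework is available to R, the forward and
backward passes are implemented directly (Rcpp/Armadillo): convolutions as
27 shifted GEMMs, exact adjoints for pooling and trilinear upsampling, and
hand-derived batch-norm and loss gradients. The test suite verifies every
gradient against central finite differences (interior tolerances around
1e-9 in the dedicated checks).

## Losses

The supervised objective averages `0.5 * (cross-entropy + soft Dice)` over
the S heads (`supervised_loss()`). The soft Dice excludes the background
class, the usual convention when foreground voxels are rare; cross-entropy
clamps probabilities at 1e-7 before the log.

The unsupervised objective (`unsupervised_loss()`) is an
uncertainty-rectified pyramid consistency: with per-scale predictions
`p_s` and pyramid mean `pc`, per-voxel discrepancies `D_s = KL(pc || p_s)`
define rectification weights `exp(-D_s)`, and

```
Lu = (1/S) * sum_s [ mean(exp(-D_s) * (p_s - pc)^2) / (mean(exp(-D_s)) + eps)
                     + mean(D_s) ]
```

Both the KL direction and eps are exposed as configuration. The analytic
gradient flows through the mean, the weights and the discrepancy term (no
stop-gradients); this is verified against finite differences.

The two terms combine as `Ltotal = Ls + lambda(t) * Lu` with the Gaussian
warm-up `lambda(t) = wmax * exp(-5 * (1 - t/tmax)^2)`, so consistency
pressure is negligible early and reaches `wmax` at the final step. `wmax`
defaults to 0.1, the customary value for this family of consistency
objectives. The consistency term is applied to the *unlabeled* patches of
each batch by default: unlabeled data carry the consistency signal while
labeled patches are driven by supervision. A `lu_on_labeled` flag restores
the full-batch variant; in our phantom pilots the full-batch variant
degraded held-out Dice below supervised-only training, consistent with the
labeled patches receiving two competing gradients.

## Probability-aware weighted random cropping

For each labeled volume, `build_crop_list()` marks every depth start index
`j` whose window `[j, j + window_depth)` contains strictly more than `k`
foreground voxels (both lesion classes count; default `k = 50`). The lists
are summed over labeled volumes (`aggregate_crop_lists()`) and the result
is used as a categorical distribution over depth starts for *all* training
crops, labeled and unlabeled alike. H/W starts are uniform: the probability
list is defined on the depth axis only, the axis along which lesions are
sparse in anisotropic acquisitions. If every weight is zero the sampler
falls back to a uniform choice among valid starts rather than failing. The
aggregate list is built once before training, since labels do not change.
The implementation uses a cumulative-sum sliding window and is tested
against a brute-force slab-counting oracle.

## Training

`train_ucppa()` draws batches of 2 labeled + 2 unlabeled patches (the
published batch composition), applies random flips and in-plane 90-degree
rotations, and optimizes with SGD (momentum 0.9, weight decay 1e-4, initial
learning rate 0.001). The learning rate is halved when the windowed mean
supervised loss stops improving (window 50 steps, patience 20 windows by
default) — a reduce-on-plateau rule with conventional defaults, since none
are published. When `wmax = 0` the unlabeled stream is skipped entirely and
training reduces to supervised deep supervision. All randomness (cropping,
augmentation, batching, initialization) derives from two explicit seeds,
and two runs with the same seeds produce identical loss histories.

## Inference and metrics

`sliding_window_predict()` tiles the volume with overlapping patches,
averages the class probabilities of the highest-resolution head in overlap
regions, and takes the per-voxel argmax (ties resolve to the lower class
index). Only the finest head is used at inference; averaging all heads is a
possible alternative we did not adopt, since the finest head is the one
supervised at output resolution. Dice is `2|A n B| / (|A| + |B|)`; HD95 is
the 95th percentile of the pooled directed surface distances, computed in
millimetres using the voxel spacing (voxel-unit distances would not be
comparable across anisotropic scans). Empty-vs-empty masks score Dice 1 and
HD95 0; empty-vs-nonempty returns the sentinel `Inf`.

# Renderer

## Non-scalar volumes and the 2D transfer function

`non_scalar_volume()` pairs a normalized intensity volume with a mask of
continuous values `g` in [0, 1], obtained from discrete labels through a
user-set map (defaults: background 0.15, SNFH 0.6, tumor 1.0 — the bridge
between the discrete label set and the continuous importance domain). The
transfer function (`transfer_function_2d()`) is piecewise-linear in
intensity, yielding a base material (opacity, RGB albedo, smoothness,
Henyey-Greenstein asymmetry), and its second dimension is the importance
transfer function

```
I(g; a) = (1 - exp(-a g)) (1 + exp(-a)) / ((1 + exp(-a g)) (1 - exp(-a)))
        = tanh(a g / 2) / tanh(a / 2)
```

which fixes I(0) = 0, I(1) = 1 and is strictly increasing. Opacity,
smoothness and each albedo channel are multiplied by I; the phase
asymmetry is left unmodulated (shape of the scattering lobe is not an
"amount" attribute, and only opacity, smoothness and albedo are described
as readjusted). The precision parameter defaults to a = 4; values a <= 1
are accepted with a warning since the map then barely sharpens. Extinction
is `opacity * density_scale` (default 0.25 / mm), since opacity and
extinction are not separated anywhere upstream.

## Transport

The renderer solves the radiative transfer equation by null-scattering
(delta-tracking) path tracing: within each macrocell, tentative collisions
are drawn from the exponential law at the cell's majorant extinction and
accepted with probability `sigma_t(x) / majorant`. Majorants are built per
8-voxel cell from the interval maximum of the piecewise-linear opacity map
(endpoints plus interior control points) over the cell's intensity range,
expanded by one voxel because trilinear interpolation reaches neighbouring
voxels, and multiplied by the maximal importance in the cell — a
conservative bound that the sampler asserts at every tentative collision.
Rays traverse the macrocell grid with a 3D-DDA. Shadow transmittance
toward the single directional light uses ratio tracking (lower variance
than binary delta tracking at the same majorant machinery); escaping rays
collect a constant ambient term. Intensity is sampled trilinearly; mask
values use nearest-neighbour lookup so labels never blend across classes.

Shading is a stochastic hybrid: the surface-ness weight
`s = clamp(|grad| / threshold, 0, 1)` (threshold defaulting to the 60th
percentile of the volume's gradient magnitudes) selects between a surface
branch — a normalized cosine-power lobe around the gradient normal with
exponent `2 / (1 - smoothness + eps)^2 - 2` — and a volumetric branch —
Henyey-Greenstein sampling with the material's asymmetry. A weighted-sum
blend of both branches is the obvious alternative; the stochastic pick
keeps each path's throughput simple and unbiased. Zero-gradient points
always take the volumetric branch. Paths carry RGB throughput multiplied
by the single-scattering albedo at each real collision, with next-event
estimation toward the light and Russian roulette after bounce 3.

Per-pixel, per-sample counter-based RNG streams (hash-initialized
splitmix64) make progressive accumulation independent of pass structure:
two 8-sample passes accumulate the same numbers as one 16-sample pass (up
to floating-point summation order; resolved 8-bit images are identical),
and fixed seeds reproduce renders byte-for-byte.

A deterministic emission-absorption ray-marcher (`reference_ray_march()`)
with the same transfer function serves as a noise-free oracle for
silhouette and importance behaviour in the tests.

# The phantom generator

`generate_phantom()` emulates the geometry of the target data rather than
its radiometry: an ellipsoidal brain filled with a Gaussian-blurred random
texture (blur sigma 2 voxels, sd 0.15 around mean 1.0), one or more
superellipsoidal tumors (random orientation and exponent in [2, 4], radii
5–9 voxels) strictly inside the brain, each wrapped in a 2.5-voxel
hyperintense shell (mean 1.75) standing in for SNFH, Gaussian voxel noise
(sd 0.06; a Rician switch exists for magnitude-image realism), and air
outside. Tumor mean 1.35 against brain mean 1.0 gives tumor/brain histogram
overlap well above 5 percent — the regime in which intensity-only transfer
functions fail and mask-aware rendering is the point. The default 64x64x48
grid keeps the full pipeline runnable in minutes; phantoms are a
deterministic function of their config (including the seed).

What the phantom does *not* emulate: multi-parametric MRI, bias fields,
partial-volume effects at tissue interfaces, anatomical texture, or
realistic lesion morphology. Tests passing on phantoms therefore
demonstrate the correctness and the qualitative behaviour of the pipeline
(cropping concentrates patches on lesions; consistency regularization
helps when labels are scarce), not clinical-grade segmentation accuracy.

# Problem sizes used in the checks

The self-check suite and `scripts/acceptance.R` run everything at desk
scale on one CPU: tiny networks (base_filters 4, patch 32x32x16) trained
for 300 SGD steps on 6 labeled + 12 unlabeled phantoms (33% labeled
fraction), evaluated on 4 held-out phantoms; both the test suite and the
acceptance script compare medians over 2 seeds (the script derives its
seeds from `--seed`). Renderer statistics use 1e4–1e5 samples; end-to-end render
identities use 64x64 pixels at 32 samples per pixel. These sizes are the
package's reference configuration for reproducible self-checks; the same
code paths scale to full-size volumes (240x240x155, base_filters 16, patch
128x128x32) given proportionally more compute and memory.

# Numerical choices and degenerate inputs

* Normalization statistics use all voxels (air included) and the 1/N
  variance convention; restricting to brain voxels is a plausible variant
  for real data but is not the default here.
* Zero-variance volumes refuse to normalize; all-zero crop weights fall
  back to uniform sampling; empty label sets give the documented Dice/HD95
  conventions.
* Probabilities are clamped at 1e-7 (cross-entropy) / 1e-8 (consistency
  KL) before logs; batch-norm uses eps 1e-5 and momentum 0.1 on running
  statistics; soft Dice uses eps 1e-5.
* Softmax temperature is 1; argmax ties resolve toward the lower class
  index everywhere.
* The majorant invariant (`sigma_t <= cell majorant`) is asserted during
  sampling; a violation raises an error rather than silently biasing the
  estimator.
* Axis order is (H, W, D) with depth last; crop windows and macrocell
  intervals are half-open; all indices in the cropping API are 0-based to
  match the depth-start semantics.

# Known limitations

* CPU-only; no GPU kernels, no real-time denoiser — noise-free images come
  from progressive accumulation only.
* The renderer's lighting model is one directional light plus a constant
  ambient term; no HDR environments, no spectral rendering.
* Single Henyey-Greenstein lobe per material; the surface lobe is a
  normalized cosine-power approximation, not a full microfacet BSDF.
* Training at full published scale (500 epochs on hundreds of volumes) is
  out of reach in plain R; the package targets methodological fidelity and
  desk-scale experiments rather than benchmark reproduction.
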