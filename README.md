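# segvis3d

Semi-supervised lesion segmentation and realistic volume rendering of 3D
medical images, in R.

Meningiomas — the most common primary intracranial tumors in adults — and
the surrounding non-enhancing FLAIR hyperintensity (SNFH) occupy a small
fraction of a brain MRI and overlap healthy tissue in intensity, so
classical transfer-function volume rendering cannot isolate them and
supervised segmentation needs annotations that are expensive to produce.
This package implements, at desk scale and for method developers and
visualization researchers, the full pipeline that addresses both problems:

* **Probability-aware weighted random cropping.** For each labeled volume
  with labels `y ∈ {0,1,2}^{H×W×D}`, a list `l_i` of length D marks every
  depth start `j` whose crop window holds more than `k` foreground voxels
  (default `k = 50`); the aggregate `L = Σᵢ l_i` is the categorical
  distribution from which all training crops — labeled and unlabeled —
  draw their depth starts, concentrating patches on lesion anatomy.
* **Pyramid-consistency semi-supervised training.** A V-Net-style
  encoder/decoder with deep-supervision heads produces multi-scale
  predictions `[p₁ … p_S]`. Labeled patches pay
  `L_s = (1/S) Σ_s ½(L_ce(p_s,y) + L_Dice(p_s,y))`; unlabeled patches pay
  an uncertainty-rectified consistency loss `L_u` that pulls each scale
  toward the pyramid mean, down-weighted by `exp(−KL(p_c‖p_s))` where the
  scales disagree. The total objective is `L_total = L_s + λ(t)·L_u` with
  the Gaussian warm-up `λ(t) = w_max·exp(−5(1−t/t_max)²)`.
* **Importance-driven Monte Carlo rendering.** The renderer consumes
  non-scalar voxels `v = (intensity, mask)` through a 2D transfer function:
  a piecewise-linear intensity→material map and the importance transfer
  function
  `I(g;a) = (1−e^{−ag})(1+e^{−a}) / ((1+e^{−ag})(1−e^{−a})) = tanh(ag/2)/tanh(a/2)`,
  which multiplies opacity, smoothness and albedo so low-importance tissue
  fades away. Light transport is null-scattering path tracing under a
  macrocell majorant grid with 3D-DDA traversal, hybrid
  volumetric/surface shading, ratio-tracked shadows and progressive,
  seed-reproducible accumulation. Dice and HD95 (mm) evaluate
  segmentations; a synthetic brain-phantom generator makes everything
  testable without any external dataset.

The network, its hand-derived backward pass, the losses and the renderer
are implemented in R + Rcpp/Armadillo; no deep-learning framework or GPU
is required.

## Worked example

Generate a phantom dataset, train a small semi-supervised model, segment a
held-out phantom, and render it with the lesion emphasized:

```r
library(segvis3d)

## 2 labeled + 2 unlabeled synthetic brains (64 x 64 x 48 voxels)
man <- generate_dataset(2, 2, "demo_data", seed = 1)

## tiny pyramid network, 120 SGD steps, consistency weight 0.1
fit <- train_ucppa(man,
                   pyramid_net_config(base_filters = 4, patch_size = c(32, 32, 16)),
                   training_config(steps = 120, wmax = 0.1, seed = 1))
tail(fit$history, 1)
#>     step       ls        lu lambda   ltotal    lr
#> 120  120 1.055296 0.1155629    0.1 1.066852 0.001

## segment a fresh phantom and score it
ph <- generate_phantom(phantom_config(seed = 99))
pred <- sliding_window_predict(fit$params, ph$intensity)
dice_score(pred, ph$labels, "foreground")
#> [1] 0.2983731
hd95(pred, ph$labels, "foreground", spacing = ph$labels$spacing)
#> [1] 43.02325

## render the phantom with its true mask: tumor at full importance,
## background faded (g = 0.15 -> I(0.15, 4) ~ 0.30)
nsv  <- non_scalar_volume(normalize_zmuv(ph$intensity), ph$labels)
scn  <- render_scene(nsv, default_tf())
cam  <- default_camera(nsv, width = 128, height = 128)
fb   <- render_progressive(scn, cam, render_settings(spp = 64, seed = 1))
write_image(resolve_framebuffer(fb), "phantom_render.png")
```

The loss row shows the combined objective obeying
`ltotal = ls + lambda·lu` with the warm-up at its final value
`lambda = wmax = 0.1`; the Dice/HD95 pair quantifies a deliberately small
training run (120 steps of a 4-filter network on two labeled volumes —
enough to localize the lesion region, far from converged). In the rendering, the tumor
(mask g = 1, importance 1) keeps full opacity and albedo while background
tissue (g = 0.15, importance I = 0.302 at the default precision a = 4) fades
to a translucent context.

The same pipeline is available from the shell via the bundled CLI
(`inst/cli/segvis3d`): subcommands `phantom`, `train`, `segment`,
`render`, and `demo`, which chains all four on phantoms.

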