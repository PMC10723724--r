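# salseg

Selective level-set image segmentation driven by edge, region and saliency
forces.

`salseg` segments objects in 2-D grayscale or RGB images (medical scans,
micrographs, natural scenes) with a hybrid active-contour model. It is
aimed at image-analysis practitioners who need a classical,
fully deterministic, training-free segmenter that handles intensity
inhomogeneity and noise, and that can extract *one chosen object* from a
multi-object scene by seeding a region of interest inside it.

## The model

The contour is the zero level set of a scalar field φ(x, y) evolved by the
reduced flow

    ∂φ/∂t = α · F(x, y) · |∇φ|

where the driving force blends three normalized per-pixel terms,

    F = s · ( w · F_DoG + (1 − w) · F_SPF ) + (1 − s) · F_SAL ,

each bounded in [−1, 1]:

- **F_DoG** — Difference-of-Gaussians edge force,
  `(I ∗ G_σ1) − (I ∗ G_σ2)` with σ1 < σ2, whose zero-crossings track
  intensity edges;
- **F_SPF** — global signed pressure force,
  `(I − (j1 + j2)/2) / max|I − (j1 + j2)/2|`, built from the Chan–Vese
  region means j1 (inside) and j2 (outside) weighted by the smoothed
  Heaviside `H_ε(φ) = ½(1 + (2/π) arctan(φ/ε))`;
- **F_SAL** — adaptive saliency force: the same signed-pressure construction
  applied to the saliency map `S = |mean(I) − I ∗ G|`, via its region means
  s1, s2.

`s` trades the intensity-driven pair against saliency (large `s` for
homogeneous/inhomogeneous intensity scenes, small `s` for textured scenes);
`w` trades edge against region information. φ is initialized as a
three-valued constant (+ρ inside the seed region, 0 on its boundary, −ρ
outside) and, after every explicit-Euler step, is reset to ±ρ and smoothed
with a Gaussian kernel — a reinitialization-free regularization that also
keeps the evolution confined to a narrow band around the interface, which
is what makes the segmentation selective. Results are scored with Dice,
accuracy, specificity, Jaccard and F1 computed from pixel confusion
counts.

## Worked example

Segment a biased, noisy synthetic disk seeded by a small circle at its
center:

```r
library(salseg)

scene <- render_scene(scene_spec(
  shape   = c(128, 128),
  objects = list(disk(63.5, 63.5, 30, intensity = 0.9)),
  background = 0.1,
  bias  = list(type = "linear", strength = 0.5),
  noise = list(type = "gaussian", sd = 0.05),
  seed  = 42))

res <- segment(scene$image, seg_params(), roi_circle(63.5, 63.5, 10))
res
#> Level-set segmentation result
#>   image: 128 x 128, foreground pixels: 2828 (17.3%)
#>   iterations: 16 (converged)

as.data.frame(compute_metrics(confusion_counts(res$mask, scene$mask)))
#>   dsc accuracy specificity jaccard f1
#> 1   1        1           1       1  1
```

Despite a 50 % multiplicative bias ramp and σ = 0.05 Gaussian noise, the
converged mask matches the ground-truth disk pixel for pixel (Dice = 1).
The per-iteration trace (`res$trace`) records the evolving region means
j1, j2, s1, s2 and the fraction of mask pixels changed, which drives the
stopping rule.

The same run from a shell:

```sh
salseg_cli=$(Rscript -e 'cat(system.file("cli", "salseg", package = "salseg"))')
Rscript "$salseg_cli" segment --image scene.png --roi circle:63,63,10 \
  --out mask.png --overlay overlay.png
Rscript "$salseg_cli" metrics --pred mask.png --truth truth.png
```

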