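---
title: "Hybrid level-set segmentation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid level-set segmentation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salseg)
```

## The model

`salseg` evolves an implicit contour — the zero set of a scalar field
$\varphi(x,y)$ — under the reduced flow

$$\frac{\partial\varphi}{\partial t} = \alpha\, F(x,y)\, |\nabla\varphi|,$$

discretized by explicit Euler with step $\Delta t$. The classical geodesic
formulation carries two further terms, a curvature penalty
$\mathrm{div}(\nabla\varphi/|\nabla\varphi|)$ and an advection term
$\nabla F\cdot\nabla\varphi$; both are deliberately absent here. Their
stabilizing role is taken over by smoothing $\varphi$ with a Gaussian
kernel after every step, which also removes any need to maintain or
reinitialize a signed distance function.

The scalar force blends three ingredients, each normalized to $[-1,1]$ so
the blend weights act on a common scale:

* **Edge term** $F_{\mathrm{DoG}} = (I * G_{\sigma_1}) - (I * G_{\sigma_2})$,
  $\sigma_1 < \sigma_2$, rescaled by its maximum absolute value. Its
  zero-crossings sit on intensity edges; the sign is positive just inside a
  bright object's rim and negative just outside, so the term sharpens the
  contour's landing on the boundary.
* **Region term** (signed pressure force)
  $F_{\mathrm{SPF}} = \dfrac{I - (j_1+j_2)/2}{\max|I - (j_1+j_2)/2|}$,
  where $j_1, j_2$ are the interior/exterior means of $I$ weighted by the
  smoothed Heaviside
  $H_\varepsilon(\varphi) = \tfrac12\bigl(1 + \tfrac{2}{\pi}
  \arctan(\varphi/\varepsilon)\bigr)$ and its complement. Pixels brighter
  than the mid-mean push the contour outward, darker pixels pull it inward.
* **Saliency term** $F_{\mathrm{SAL}}$: the identical signed-pressure
  construction applied to the saliency map
  $S = |\,\overline{I} - I * G_{\sigma_{\mathrm{sal}}}|$ with its own region
  means $s_1, s_2$. It emphasizes regions that deviate from the image's
  global brightness, which carries the load on textured scenes where raw
  intensity is uninformative.

The combination used by default is the *grouped* form

$$F = s\,\bigl(w\,F_{\mathrm{DoG}} + (1-w)\,F_{\mathrm{SPF}}\bigr) +
      (1-s)\,F_{\mathrm{SAL}},$$

a convex combination, hence itself bounded in $[-1,1]$. An alternative
scoping, $s\,w\,F_{\mathrm{DoG}} + (1-w)F_{\mathrm{SPF}} +
(1-s)F_{\mathrm{SAL}}$, in which the region term escapes the $s$
attenuation, is retained behind `literal_eq2 = TRUE`. The grouped form is
the default because $s$ is documented throughout as the dial between the
*intensity pair* and saliency, and because only the grouped form keeps the
combined force a convex blend; the two coincide at $w$ or $s$ equal to 0
or 1. Similarly, the saliency force's normalizing denominator uses
$\max|S - (s_1+s_2)/2|$ — the deviation of the *saliency map*, not of the
intensity image — since only that choice bounds the ratio by 1 and mirrors
the SPF construction.

The model assumes a scalar intensity field: RGB input is collapsed to
Rec. 601 luminance ($0.299R + 0.587G + 0.114B$) before anything else, and
all intensities are normalized to $[0,1]$ (both SPF and SAL are invariant
to affine intensity maps, so normalization only fixes the meaning of
$\varepsilon$ and $\alpha$ across bit depths).

## Initialization, selectivity and the binary reset

$\varphi$ starts as a three-valued constant field: $+\rho$ strictly inside
the seed region, $0$ on its one-pixel boundary (interior pixels 4-adjacent
to the exterior), $-\rho$ outside. Interior-positive is a pure convention:
running the mirrored dynamics on $-\varphi$ reproduces the complemented
mask bit for bit (the update, reset and smoothing are all odd functions of
$\varphi$), so nothing is lost by fixing it; the choice makes
$H_\varepsilon(\varphi)\approx 1$ inside, so $j_1$ is the mean of the
seeded object.

Because the update is proportional to $|\nabla\varphi|$, pixels where
$\varphi$ is flat do not move — this is the mechanism that confines the
evolution to the neighborhood of the interface and lets a seed placed in
one object ignore every other object in the scene. Two details make it
work in practice:

1. **Binary reset.** Before each smoothing pass, $\varphi$ is reset to
   $\rho\,\mathrm{sign}(\varphi)$. Without the reset the force keeps
   inflating $\varphi$ inside the captured region without bound, and the
   per-iteration Gaussian smoothing then spreads those growing values
   across the image; in two-object scenes the gradient tails eventually
   reach the second object, which is then recruited wholesale. With the
   reset the amplitude is capped at $\rho$, the gradient support stays
   within a few kernel radii of the interface, and the two-disk selective
   scene is segmented with zero leak. The smooth-profile variant remains
   available (`binary_reset = FALSE`) for experimentation.
2. **No curvature term.** The reset-plus-smoothing cycle itself induces a
   weak motion by mean curvature (threshold dynamics): on a force-free,
   constant image a seeded rectangle keeps its straight edges but rounds
   its corners by about a pixel over tens of iterations. This is the
   regularization doing its job; it bounds how literally "zero force means
   a frozen contour" should be read.

## Iteration and stopping

Per iteration: recompute $j_1, j_2, s_1, s_2$ from the current $\varphi$
(the DoG force and the saliency map depend only on the image and are
computed once), rebuild $F_{\mathrm{SPF}}$ and $F_{\mathrm{SAL}}$, combine,
take one Euler step, reset and smooth, and record the fraction of mask
pixels that changed. The run stops when that fraction has stayed below
`tol` for `patience` consecutive iterations, or at `max_iterations`. The
changed-pixel fraction was chosen as the criterion because it is cheap,
scale-free, and directly measures what a user cares about (a stable mask);
on the synthetic suite the method converges in 20–60 iterations, well
inside the default cap of 300.

## Parameters

| name | default | unit | role |
|---|---|---|---|
| `s` | 0.9 | — | intensity pair vs. saliency; raise toward 1 on intensity-driven scenes, drop near 0 on textured ones |
| `w` | 0.5 | — | edge vs. region within the intensity pair |
| `sigma1`, `sigma2` | 1, 2 | px | DoG scales; widen the gap (e.g. 1 and 10) for noisy images |
| `sigma_reg` | 1 | px | per-iteration level-set smoothing |
| `sigma_sal` | 2 | px | saliency-map smoothing (no canonical value exists; 2 px suppresses pixel noise without erasing small objects) |
| `rho` | 1 | — | initialization amplitude; any positive value works, 1 keeps $H_\varepsilon$ well inside its linear range |
| `eps` | 1.5 | — | Heaviside transition width |
| `alpha` | 20 | — | propagation gain; the one knob that may need per-image adjustment (larger = faster fronts, more overshoot) |
| `dt` | 1 | — | Euler step |
| `tol`, `patience` | 1e-4, 5 | — | stopping rule |
| `max_iterations` | 300 | — | cap |

## Numerical choices

* Gaussian kernels are truncated at radius $\lceil 3\sigma\rceil$ and
  renormalized; boundaries use half-sample reflection, which conserves the
  field's total mass exactly and avoids edge darkening.
* Every normalizing denominator is guarded at $10^{-10}$; a force whose
  pre-normalization maximum falls below the guard is defined as the zero
  field, so constant images produce no spurious motion.
* Region means with near-zero weight mass on one side (below
  $10^{-6}$ of the pixel count) emit a warning rather than an error: this
  occurs only when the contour has collapsed or swallowed the frame, and
  the guarded division still returns finite values.
* Gradient magnitude uses central differences in the interior and one-sided
  differences on the border, exact for affine fields.
* Ties: `extract_mask` assigns $\varphi = 0$ (the contour itself) to the
  background; the ROI boundary ring is therefore excluded from the initial
  mask.
* Evaluation metrics with a zero denominator (e.g. specificity on a
  truth mask without background) are reported as `NA`, never coerced, so
  set averages are not corrupted.

## The synthetic generator

`scene_spec()`/`render_scene()` produce two-phase scenes — disks and
rectangles on a constant background — optionally degraded by a
multiplicative bias field $1 + \text{strength}\,( \text{ramp} - 0.5)$
(linear diagonal or centered Gaussian bump; the multiplicative form matches
the standard bias-field model of inhomogeneity correction) and by Gaussian
or salt-and-pepper noise from a seeded generator. Ground-truth masks are
the exact pre-degradation object supports. `standard_suite()` fixes six
named regimes (homogeneous, bias 0.5, bias + Gaussian σ = 0.05,
salt-and-pepper 2 %, two-disk selective, contrast 0.15 weak boundary) at
256 × 256 — sizes at which a full run takes well under a minute — with
intensities 0.9 on 0.1 chosen to mimic a bright organ or lesion on a dark
background at roughly 20 % area fraction.

What passing these scenes shows — and what it does not: the suite
exercises inhomogeneity, two noise families, low contrast and
multi-object selectivity with piecewise-constant truth, but real images
add texture, partial-volume boundaries, anisotropic structure and
correlated noise. Success on the suite demonstrates the mechanics of the
forces and the selectivity property, not clinical-grade accuracy; on real
data `alpha`, `s`, `w` and the DoG scales typically need per-image tuning,
which is the method's main practical limitation (along with its
slice-wise, purely 2-D view of volumetric data).

## Problem sizes used in the tests

Unit tests run on 9–64 px grids where oracles (dense direct convolution,
closed-form Heaviside sums, hand-evaluated force examples) are exact and
fast; the end-to-end property checks and the acceptance script use the
256 × 256 suite. The dense-convolution oracle is an independent
reimplementation (full 2-D kernel, explicit loops) kept in the test
helpers, never called by the package itself.
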