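# Per-pixel driving forces for the level-set evolution: the
# Difference-of-Gaussians edge force, the global signed-pressure-force
# region term, the saliency map and its adaptive force, and their weighted
# combination. All component forces are normalized to [-1, 1] so the blend
# weights s and w act on a common scale.

# guard on every denominator; a constant input yields a zero force field
.denom_guard <- 1e-10

#' Difference-of-Gaussians edge force
#'
#' Computes `blur(img, sigma1) - blur(img, sigma2)` with `sigma1 < sigma2`,
#' then scales the result by its maximum absolute value so the force lies in
#' \[-1, 1\]. The zero-crossings of the DoG track locations of rapid
#' intensity change, so the sign of the force flips across object
#' boundaries: positive just inside a bright object's rim, negative just
#' outside. A constant image (DoG identically below the guard threshold)
#' gives a zero field.
#'
#' Wider (sigma1, sigma2) pairs suppress noise at the cost of fine detail;
#' for noisy images the gap between the two standard deviations should be
#' chosen large.
#'
#' @param img Numeric matrix of intensities.
#' @param sigma1,sigma2 Standard deviations of the narrow and wide Gaussians
#'   (pixels); `0 < sigma1 < sigma2` is required.
#' @return A force matrix in \[-1, 1\].
#' @export
compute_dog <- function(img, sigma1, sigma2) {
  if (!is.numeric(sigma1) || !is.numeric(sigma2) ||
      length(sigma1) != 1L || length(sigma2) != 1L ||
      !is.finite(sigma1) || !is.finite(sigma2) ||
      sigma1 <= 0 || sigma1 >= sigma2) {
    stop("require 0 < sigma1 < sigma2", call. = FALSE)
  }
  d <- gaussian_blur(img, sigma1) - gaussian_blur(img, sigma2)
  normalize_max_abs(d)
}

#' Region means weighted by the smoothed Heaviside of the level set
#'
#' The Chan-Vese style means of a field over the interior and exterior of
#' the evolving contour:
#' `j1 = sum(f * H) / sum(H)` and `j2 = sum(f * (1 - H)) / sum(1 - H)`,
#' where `H = heaviside(phi, eps)`. With the interior-positive sign
#' convention, `j1` is the interior mean. Used both for image intensities
#' (feeding the signed pressure force) and for the saliency map (feeding
#' the adaptive saliency force).
#'
#' Denominators are guarded; a region whose weight mass falls below
#' `1e-6 * npixels` is degenerate and triggers a warning.
#'
#' @param f Numeric matrix (intensity image or saliency map).
#' @param phi Level-set matrix of the same shape.
#' @param eps Heaviside regularization width; must be > 0.
#' @return A list with elements `m1` (inside mean) and `m2` (outside mean).
#' @export
region_means <- function(f, phi, eps) {
  if (!identical(dim(f), dim(phi))) {
    stop("field and phi must share a shape", call. = FALSE)
  }
  h <- heaviside(phi, eps)
  w1 <- sum(h)
  w2 <- sum(1 - h)
  if (min(w1, w2) < 1e-6 * length(f)) {
    warning("degenerate region: near-zero weight mass on one side of the contour")
  }
  list(m1 = sum(f * h) / max(w1, .denom_guard),
       m2 = sum(f * (1 - h)) / max(w2, .denom_guard))
}

#' @rdname region_means
#' @param sal Saliency matrix from [compute_saliency_map()].
#' @export
saliency_means <- function(sal, phi, eps) {
  region_means(sal, phi, eps)
}

#' Global signed pressure force
#'
#' `SPF = (I - (j1 + j2)/2) / max|I - (j1 + j2)/2|`: positive exactly where
#' the intensity exceeds the midpoint of the two region means, negative
#' below it, bounded in \[-1, 1\] by construction. Acting through the
#' level-set update, it inflates the contour where the local intensity
#' looks like the interior and deflates it where it looks like the
#' exterior. A constant image yields a zero field (guarded denominator).
#'
#' @param img Numeric matrix of intensities.
#' @param means List with `m1`, `m2` as returned by [region_means()].
#' @return A force matrix in \[-1, 1\].
#' @export
compute_spf <- function(img, means) {
  mid <- (means$m1 + means$m2) / 2
  if (!is.finite(mid)) stop("region means must be finite", call. = FALSE)
  normalize_max_abs(img - mid)
}

#' Saliency map
#'
#' `S(x, y) = |mean(I) - (I * G_sigma)(x, y)|`: the absolute deviation of
#' the Gaussian-smoothed image from the global mean intensity. Regions that
#' stand out from the average brightness of the image get high saliency;
#' a constant image has zero saliency everywhere.
#'
#' @param img Numeric matrix of intensities.
#' @param sigma_sal Standard deviation of the smoothing Gaussian (pixels).
#' @return A non-negative matrix of the same shape.
#' @export
compute_saliency_map <- function(img, sigma_sal) {
  abs(mean(img) - gaussian_blur(img, sigma_sal))
}

#' Adaptive saliency force
#'
#' The saliency analogue of the signed pressure force:
#' `SAL = (S - (s1 + s2)/2) / max|S - (s1 + s2)/2|`, where `s1`, `s2` are
#' the interior/exterior means of the saliency map under the current
#' contour. Positive where the saliency exceeds the mid-mean, bounded in
#' \[-1, 1\]; a constant saliency map yields a zero field.
#'
#' @param sal Saliency matrix from [compute_saliency_map()].
#' @param means List with `m1` (= s1), `m2` (= s2) from
#'   `region_means(sal, phi, eps)`.
#' @return A force matrix in \[-1, 1\].
#' @export
compute_sal_force <- function(sal, means) {
  compute_spf(sal, means)
}

#' Weighted combination of the edge, region and saliency forces
#'
#' Default (grouped) form:
#' `F = s * (w * F_DoG + (1 - w) * F_SPF) + (1 - s) * F_SAL`,
#' a convex combination whenever the components lie in \[-1, 1\], so the
#' result does too. `s` trades the intensity-driven pair (edge + region)
#' against the saliency term: large `s` suits homogeneous or
#' intensity-inhomogeneous scenes, small `s` lets saliency lead on textured
#' scenes. `w` trades edge against region information within the intensity
#' pair: `w` near 1 emphasizes the DoG edge force, near 0 the global region
#' force.
#'
#' With `literal_eq2 = TRUE` the alternative scoping
#' `F = s * w * F_DoG + (1 - w) * F_SPF + (1 - s) * F_SAL` is used, in
#' which the region term is not attenuated by `s`; this form is not a
#' convex combination and can leave \[-1, 1\].
#'
#' @param dog,spf,sal Component force matrices of a common shape.
#' @param s,w Blend weights in \[0, 1\].
#' @param literal_eq2 Use the alternative (ungrouped) scoping.
#' @return The combined force matrix.
#' @export
combine_forces <- function(dog, spf, sal, s, w, literal_eq2 = FALSE) {
  for (x in list(s = s, w = w)) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
      stop("s and w must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!identical(dim(dog), dim(spf)) || !identical(dim(dog), dim(sal))) {
    stop("force fields must share a shape", call. = FALSE)
  }
  if (isTRUE(literal_eq2)) {
    s * w * dog + (1 - w) * spf + (1 - s) * sal
  } else {
    s * (w * dog + (1 - w) * spf) + (1 - s) * sal
  }
}

# Scale a field by its max absolute value; a field that is (numerically)
# constant zero maps to the zero field rather than dividing by ~0.
normalize_max_abs <- function(f) {
  m <- max(abs(f))
  if (!is.finite(m)) stop("force field contains non-finite values",
                          call. = FALSE)
  if (m < .denom_guard) return(f * 0)
  f / m
}
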