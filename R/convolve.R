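#' Separable Gaussian smoothing of a 2-D field
#'
#' Convolves a matrix with an isotropic Gaussian kernel, applied separably
#' along rows and columns. The 1-D kernel is truncated at radius
#' `ceiling(3 * sigma)` and renormalized to unit sum, so constants pass
#' through unchanged. Boundaries are handled by half-sample reflection
#' (edge pixel repeated: `c b a | a b c`), which conserves the total sum of
#' the field under the normalized symmetric kernel.
#'
#' This is the single smoothing primitive behind the Difference-of-Gaussians
#' edge force, the saliency map and the per-iteration level-set
#' regularization, so all of them share one truncation and boundary
#' convention.
#'
#' @param img Numeric matrix (any real values; intensities or a level-set
#'   field).
#' @param sigma Standard deviation of the Gaussian, in pixels; must be > 0.
#' @return A matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("img must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a positive number", call. = FALSE)
  }
  k <- gaussian_kernel1d(sigma)
  convolve_separable(img, k)
}

# Truncated, normalized 1-D Gaussian; radius ceiling(3*sigma)
gaussian_kernel1d <- function(sigma) {
  r <- as.integer(ceiling(3 * sigma))
  x <- seq.int(-r, r)
  k <- exp(-(x^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable symmetric FIR filter with half-sample reflect padding.
# Works column-wise twice (transpose in between) so the inner loop is a
# vectorized weighted sum of row-shifted copies.
convolve_separable <- function(img, k) {
  t(filter_cols(t(filter_cols(img, k)), k))
}

# Half-sample reflection of arbitrary integer indices onto 1..n
# (pattern ... c b a | a b c ... z | z y x ...), periodic with period 2n.
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

filter_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  if (r == 0L) return(m * k)
  idx <- reflect_index(seq.int(1L - r, n + r), n)
  pad <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}
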