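# Independent oracles and small fixture builders shared across the suite.

# Dense direct 2-D Gaussian convolution: full 2-D kernel (outer product of
# truncated 1-D Gaussians, radius ceiling(3*sigma), unit sum), explicit
# per-pixel loops, half-sample reflect indexing. Deliberately written
# without reusing any package internals so it can stand as an oracle.
dense_blur_oracle <- function(img, sigma) {
  r <- ceiling(3 * sigma)
  x <- -r:r
  k1 <- exp(-x^2 / (2 * sigma^2))
  k2 <- outer(k1, k1)
  k2 <- k2 / sum(k2)
  h <- nrow(img); w <- ncol(img)
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    ri <- refl(i + x, h)
    for (j in seq_len(w)) {
      cj <- refl(j + x, w)
      out[i, j] <- sum(k2 * img[ri, cj])
    }
  }
  out
}

# two-phase disk image without going through the scene generator
two_phase_disk <- function(n = 32, radius = n / 4, fg = 0.9, bg = 0.1) {
  ctr <- (n - 1) / 2
  rr <- matrix(0:(n - 1), n, n)
  cc <- t(rr)
  inside <- (rr - ctr)^2 + (cc - ctr)^2 <= radius^2
  img <- matrix(bg, n, n)
  img[inside] <- fg
  list(image = img, inside = inside)
}

# shortest distance from each TRUE pixel of a to the TRUE set of b
max_boundary_distance <- function(a, b) {
  pa <- which(a, arr.ind = TRUE)
  pb <- which(b, arr.ind = TRUE)
  stopifnot(nrow(pa) > 0, nrow(pb) > 0)
  max(vapply(seq_len(nrow(pa)), function(i) {
    sqrt(min((pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2))
  }, numeric(1)))
}

# boundary pixels of a logical mask (4-adjacency, image border is outside)
mask_boundary <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  m & !(pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
          pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)])
}

dice_of <- function(pred, truth) {
  compute_metrics(confusion_counts(pred, truth))$dsc
}
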