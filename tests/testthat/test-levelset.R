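# Level-set primitives and the segmentation loop.

test_that("smoothed Heaviside hits its closed-form anchor points", {
  expect_identical(heaviside(0, 1.5), 0.5)
  expect_equal(heaviside(1.5, 1.5), 0.75, tolerance = 1e-12)  # atan(1) = pi/4
  expect_equal(heaviside(1e6, 1.5), 1, tolerance = 1e-5)
  expect_equal(heaviside(-1e6, 1.5), 0, tolerance = 1e-5)

  x <- seq(-10, 10, by = 0.25)
  expect_true(all(diff(heaviside(x, 1.5)) > 0))               # strictly increasing
  expect_equal(heaviside(-x, 2), 1 - heaviside(x, 2), tolerance = 1e-12)
  expect_error(heaviside(0, 0), "positive")
})

test_that("initialization is three-valued with a 4-adjacent zero boundary", {
  st <- initialize_phi(c(10, 10), roi_rect(2, 2, 8, 8), rho = 1)
  expect_s3_class(st, "level_set_state")
  expect_true(all(st$phi %in% c(-1, 0, 1)))
  expect_identical(st$phi[1, 1], -1)                 # corner is outside
  # boundary ring of the 6x6 block is 0, its 4x4 core is +1
  expect_true(all(st$phi[3:8, 3] == 0))
  expect_true(all(st$phi[4:7, 4:7] == 1))
  expect_identical(st$iteration, 0L)
  expect_length(st$changed_fraction_history, 0)

  # |phi| <= rho everywhere for any rho
  st2 <- initialize_phi(c(12, 15), roi_circle(6, 7, 4), rho = 2.5)
  expect_lte(max(abs(st2$phi)), 2.5)
})

test_that("mask-kind ROI round-trips to its strict interior", {
  m <- matrix(0L, 12, 12); m[4:9, 3:10] <- 1L
  st <- initialize_phi(c(12, 12), roi_mask(m), rho = 1)
  interior <- m == 1L & !mask_boundary(m == 1L)
  expect_identical(extract_mask(st$phi), matrix(as.integer(interior), 12, 12))

  # full-image ROI: only the border ring is not positive
  full <- matrix(1L, 8, 8)
  stf <- initialize_phi(c(8, 8), roi_mask(full), rho = 1)
  expect_true(all(stf$phi[2:7, 2:7] == 1))
  expect_true(all(stf$phi[1, ] == 0) && all(stf$phi[, 8] == 0))
  expect_true(!any(stf$phi == -1))
})

test_that("invalid ROIs are rejected", {
  expect_error(initialize_phi(c(10, 10), roi_rect(2, 2, 2, 8), 1), "empty")
  expect_error(initialize_phi(c(10, 10), roi_rect(-1, 0, 5, 5), 1),
               "out of bounds")
  expect_error(initialize_phi(c(10, 10), roi_circle(5, 5, 20), 1),
               "out of bounds")
  expect_error(initialize_phi(c(10, 10), roi_mask(matrix(0L, 10, 10)), 1),
               "empty")
  expect_error(initialize_phi(c(10, 10), roi_rect(2, 2, 8, 8), rho = 0),
               "positive")
})

test_that("gradient magnitude is exact on affine fields", {
  expect_true(all(gradient_magnitude(matrix(3.7, 9, 9)) == 0))

  ramp <- matrix(0:8, 9, 9, byrow = TRUE)          # phi = column index
  expect_true(all(gradient_magnitude(ramp) == 1))

  rr <- matrix(0:8, 9, 9)
  plane <- 3 * rr + 4 * t(rr)                       # |grad| = 5
  g <- gradient_magnitude(plane)
  expect_true(all(abs(g - 5) < 1e-12))

  expect_error(gradient_magnitude(matrix(0, 2, 5)), "3x3")
})

test_that("one evolution step follows phi + dt*alpha*F*|grad phi|", {
  st <- initialize_phi(c(9, 9), roi_rect(2, 2, 7, 7), 1)

  same <- evolve_step(st, matrix(0, 9, 9), alpha = 20, dt = 1)
  expect_identical(same$phi, st$phi)
  expect_identical(same$iteration, 1L)

  ramp <- matrix(0:8, 9, 9, byrow = TRUE)
  st$phi <- ramp
  up <- evolve_step(st, matrix(1, 9, 9), alpha = 1, dt = 1)
  expect_equal(up$phi, ramp + 1, tolerance = 1e-12)

  # doubling alpha and halving dt is the same single-step update
  set.seed(31)
  f <- matrix(runif(81, -1, 1), 9, 9)
  st$phi <- matrix(rnorm(81), 9, 9)
  a <- evolve_step(st, f, alpha = 2, dt = 0.5)
  b <- evolve_step(st, f, alpha = 1, dt = 1)
  expect_identical(a$phi, b$phi)

  expect_error(evolve_step(st, matrix(NA_real_, 9, 9), 1, 1), "non-finite")
  expect_error(evolve_step(st, f, 1, dt = 0), "positive")
})

test_that("regularization preserves constants and mass, keeps the step edge put", {
  const <- matrix(2.5, 10, 10)
  expect_equal(regularize(const, 1), const, tolerance = 1e-12)

  set.seed(6)
  phi <- matrix(rnorm(100), 10, 10)
  expect_equal(sum(regularize(phi, 1)), sum(phi),
               tolerance = 1e-10 * max(1, abs(sum(phi))))

  # sharp +-rho step: smoothed profile is monotone and its zero-crossing
  # stays within 1 px of the step
  step <- matrix(rep(c(-1, 1), each = 10), 20, 20, byrow = TRUE)  # cols 1-10 = -1
  sm <- regularize(step, 1)
  mid <- sm[10, ]
  expect_true(all(diff(mid) >= -1e-12))
  zc <- which(diff(sign(mid)) > 0)
  expect_true(length(zc) == 1 && abs(zc - 10.5) <= 1)
})

test_that("mask extraction uses the interior-positive convention", {
  phi <- matrix(c(-1, 0, 0.5, 2), 2, 2)
  expect_identical(extract_mask(phi), matrix(c(0L, 0L, 1L, 1L), 2, 2))
  expect_identical(extract_mask(matrix(1, 3, 3)), matrix(1L, 3, 3))
  # sign flip complements, up to the measure-zero phi == 0 set
  phi2 <- matrix(rnorm(25), 5, 5)
  expect_identical(extract_mask(-phi2), 1L - extract_mask(phi2))
})

test_that("convergence requires `patience` consecutive quiet iterations", {
  expect_true(has_converged(c(0, 0, 0), tol = 1e-4, patience = 3))
  expect_false(has_converged(c(0.5), tol = 1e-4, patience = 3))
  expect_false(has_converged(c(0.1, 0, 0), tol = 1e-4, patience = 3))
  expect_true(has_converged(c(0.5, 0, 0, 0), tol = 1e-4, patience = 3))
  expect_false(has_converged(numeric(0), tol = 1e-4, patience = 1))
  expect_error(has_converged(c(0), tol = -1, patience = 1), "tol")
})

test_that("a constant image leaves the seeded contour (nearly) stationary", {
  img <- matrix(0.5, 48, 48)
  p <- seg_params(max_iterations = 10)
  st0 <- initialize_phi(c(48, 48), roi_rect(10, 10, 30, 30), p$rho)

  # all forces vanish on a constant image, so the evolution step itself is
  # an exact no-op ...
  zero <- combine_forces(compute_dog(img, p$sigma1, p$sigma2),
                         compute_spf(img, region_means(img, st0$phi, p$eps)),
                         matrix(0, 48, 48), p$s, p$w)
  expect_true(all(zero == 0))
  expect_identical(evolve_step(st0, zero, p$alpha, p$dt)$phi, st0$phi)

  # ... while the full loop moves the interface only by the slow curvature
  # motion of the per-iteration regularization (blur + threshold), which
  # rounds the rectangle's corners: over a short horizon the mask stays
  # close to the ROI interior
  res <- segment(img, p, roi_rect(10, 10, 30, 30))
  expect_gte(dice_of(res$mask, extract_mask(st0$phi)), 0.95)
})

test_that("segmentation recovers a two-phase disk at small scale", {
  tp <- two_phase_disk(n = 64, radius = 14)
  res <- segment(tp$image, seg_params(), roi_circle(31.5, 31.5, 6))
  truth <- matrix(as.integer(tp$inside), 64, 64)
  expect_gte(dice_of(res$mask, truth), 0.99)
  expect_true(res$converged)
  expect_lte(res$iterations_run, seg_params()$max_iterations)

  # trace records one row per completed iteration
  expect_identical(nrow(res$trace), res$iterations_run)
  expect_identical(length(res$history), res$iterations_run)
})

test_that("pure-SPF evolution lands the boundary on the true edge", {
  tp <- two_phase_disk(n = 64, radius = 14)
  res <- segment(tp$image, seg_params(s = 1, w = 0),
                 roi_circle(31.5, 31.5, 6))
  pred_b <- mask_boundary(res$mask == 1L)
  true_b <- mask_boundary(tp$inside)
  expect_lte(max_boundary_distance(pred_b, true_b), 2)
  expect_lte(max_boundary_distance(true_b, pred_b), 2)
})

test_that("runs are deterministic: repeated segmentation is bit-identical", {
  tp <- two_phase_disk(n = 48, radius = 11)
  r1 <- segment(tp$image, seg_params(), roi_circle(23.5, 23.5, 5))
  r2 <- segment(tp$image, seg_params(), roi_circle(23.5, 23.5, 5))
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$final_phi, r2$final_phi)
  expect_identical(r1$history, r2$history)
})

test_that("evolution is exactly stationary where the level set is flat", {
  st <- initialize_phi(c(32, 32), roi_circle(15.5, 15.5, 6), 1)
  far <- abs(st$phi) == 1 & gradient_magnitude(st$phi) == 0
  expect_gt(sum(far), 0)
  set.seed(2)
  f <- matrix(runif(32 * 32, -1, 1), 32, 32)
  stepped <- evolve_step(st, f, alpha = 20, dt = 1)
  expect_identical(stepped$phi[far], st$phi[far])
})

test_that("sign-convention flip with mirrored dynamics complements the mask", {
  # Running the same evolution on -phi with the force negated keeps
  # phi_flipped == -phi at every iteration, so the extracted masks are
  # complements throughout; this is what makes the interior-positive
  # convention a choice without loss of generality.
  tp <- two_phase_disk(n = 40, radius = 10)
  p <- seg_params()
  st_a <- initialize_phi(c(40, 40), roi_circle(19.5, 19.5, 5), p$rho)
  st_b <- st_a; st_b$phi <- -st_a$phi
  dog <- compute_dog(tp$image, p$sigma1, p$sigma2)
  salm <- compute_saliency_map(tp$image, p$sigma_sal)
  for (it in 1:15) {
    jm <- region_means(tp$image, st_a$phi, p$eps)
    sm <- region_means(salm, st_a$phi, p$eps)
    f <- combine_forces(dog, compute_spf(tp$image, jm),
                        compute_sal_force(salm, sm), p$s, p$w)
    st_a <- evolve_step(st_a, f, p$alpha, p$dt)
    st_b <- evolve_step(st_b, -f, p$alpha, p$dt)
    st_a$phi <- regularize(p$rho * sign(st_a$phi), p$sigma_reg)
    st_b$phi <- regularize(p$rho * sign(st_b$phi), p$sigma_reg)
    expect_identical(st_b$phi, -st_a$phi)
    expect_identical(extract_mask(st_b$phi),
                     1L - extract_mask(-st_b$phi))
  }
})
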