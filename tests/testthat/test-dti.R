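test_that("design-matrix rows expand the quadratic form", {
  r1 <- build_design_matrix(1200, matrix(c(1, 0, 0), 1))
  expect_equal(as.vector(r1), c(1200, 0, 0, 0, 0, 0))
  r2 <- build_design_matrix(1200, matrix(c(1, 1, 0) / sqrt(2), 1))
  expect_equal(as.vector(r2), c(600, 600, 0, 1200, 0, 0), tolerance = 1e-9)
  expect_identical(qr(build_design_matrix(1200, make_gradient_scheme(30)))$rank,
                   6L)
  expect_error(build_design_matrix(1200, matrix(c(2, 0, 0), 1)), "unit")
})

test_that("noise-free tensor fits recover isotropic and rotated tensors", {
  sh <- c(4, 4, 2)
  g <- make_gradient_scheme(30)
  s0 <- array(100, dim = sh)
  iso <- array(0, dim = c(sh, 6)); iso[, , , 1:3] <- 0.7e-3
  tf_iso <- tensor_field(iso, array(0.7e-3, c(sh, 3)), array(TRUE, sh),
                         c(1, 1, 1))
  fit <- fit_tensor(simulate_dwi(tf_iso, s0, 1200, g), 1200, g)
  lam <- matrix(fit$eigenvalues, ncol = 3)
  expect_lt(max(abs(lam - 0.7e-3)) / 0.7e-3, 1e-9)

  # prolate (1.7, 0.2, 0.2)e-3 under several rotations: sorted eigenvalues
  # are rotation invariant
  angles <- list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1), c(2, -1, 0.5))
  for (ax in angles) {
    R <- neuroquant:::basis_from_dir(ax / sqrt(sum(ax^2)))
    D <- R %*% diag(c(1.7e-3, 0.2e-3, 0.2e-3)) %*% t(R)
    d6 <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    tens <- array(rep(d6, each = prod(sh)), dim = c(sh, 6))
    tf <- tensor_field(tens, array(rep(c(1.7e-3, 0.2e-3, 0.2e-3),
                                       each = prod(sh)), c(sh, 3)),
                       array(TRUE, sh), c(1, 1, 1))
    fit <- fit_tensor(simulate_dwi(tf, s0, 1200, g), 1200, g)
    lam <- matrix(fit$eigenvalues, ncol = 3)
    expect_lt(max(abs(t(lam) - c(1.7e-3, 0.2e-3, 0.2e-3))) / 0.2e-3, 1e-9)
  }
})

test_that("ADC is the eigenvalue mean and FA the normalized dispersion", {
  expect_equal(adc_from_eigenvalues(1.7e-3, 0.2e-3, 0.2e-3), 0.7e-3)
  expect_equal(adc_from_eigenvalues(0.9, 0.9, 0.9), 0.9)
  expect_equal(adc_from_eigenvalues(0, 0, 0), 0)
  expect_equal(fa_from_eigenvalues(1.7, 0.2, 0.2), sqrt(4.5 / 5.94),
               tolerance = 1e-12)
  expect_equal(round(fa_from_eigenvalues(1.7, 0.2, 0.2), 4), 0.8704)
  expect_equal(fa_from_eigenvalues(0.5, 0.5, 0.5), 0)
  expect_equal(fa_from_eigenvalues(1, 0, 0), 1)
  expect_true(is.nan(fa_from_eigenvalues(0, 0, 0)))
})

test_that("FA is scale invariant and bounded, ADC between extreme eigenvalues", {
  set.seed(21)
  lam <- matrix(runif(300, 0, 3e-3), ncol = 3)
  fa <- fa_from_eigenvalues(lam)
  expect_true(all(fa >= 0 & fa <= 1 + 1e-12))
  expect_equal(fa_from_eigenvalues(lam * 1000), fa, tolerance = 1e-9)
  adc <- adc_from_eigenvalues(lam)
  expect_true(all(adc >= apply(lam, 1, min) - 1e-15))
  expect_true(all(adc <= apply(lam, 1, max) + 1e-15))
  # negative eigenvalues: kept for ADC, clamped for FA
  expect_equal(adc_from_eigenvalues(1e-3, 0, -1e-3), 0)
  expect_lte(fa_from_eigenvalues(1e-3, 1e-4, -1e-3), 1)
})

test_that("mean ADC error shrinks monotonically up the SNR ladder", {
  sh <- c(8, 8, 4)
  g <- make_gradient_scheme(30)
  s0 <- array(100, dim = sh)
  iso <- array(0, dim = c(sh, 6)); iso[, , , 1:3] <- 0.7e-3
  tf <- tensor_field(iso, array(0.7e-3, c(sh, 3)), array(TRUE, sh), c(1, 1, 1))
  err <- sapply(c(1, 0.25, 0), function(sd) {  # SNR 100 -> infinity
    fit <- fit_tensor(simulate_dwi(tf, s0, 1200, g, noise_sd = sd, seed = 13),
                      1200, g)
    abs(mean(matrix(fit$eigenvalues, ncol = 3)) - 0.7e-3)
  })
  expect_true(all(diff(err) < 0))
})

test_that("voxels with nonpositive signals are invalidated", {
  sh <- c(2, 1, 1)
  g <- make_gradient_scheme(6)
  sig <- array(50, dim = c(sh, 7))
  sig[2, 1, 1, 3] <- 0
  fit <- fit_tensor(vol_image(sig, c(1, 1, 1)), 1200, g)
  expect_true(fit$valid[1, 1, 1])
  expect_false(fit$valid[2, 1, 1])
  expect_true(is.nan(adc_map(fit)$data[2, 1, 1]))
})
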