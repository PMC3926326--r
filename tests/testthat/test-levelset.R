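# Level-set machinery: regularized Heaviside/Dirac pair, Gaussian kernel,
# local means, bias update, data forces, curvature, and the evolution.

test_that("regularized Heaviside and Dirac satisfy the analytic identities", {
  expect_equal(heaviside(0), 0.5)
  expect_equal(heaviside(1, epsilon = 1), 0.75)
  expect_equal(heaviside(1e12), 1, tolerance = 1e-9)
  expect_equal(heaviside(-1e12), 0, tolerance = 1e-9)
  x <- seq(-5, 5, by = 0.25)
  expect_equal(heaviside(-x), 1 - heaviside(x))
  expect_true(all(diff(heaviside(x)) > 0))
  expect_equal(dirac(0, 1), 1 / pi)
  expect_equal(dirac(-x), dirac(x))
  # quadrature: the Dirac mass over a wide interval is ~1
  q <- stats::integrate(function(t) dirac(t, 1), -100, 100)$value
  expect_equal(q, 1, tolerance = 1e-2)
  # dH/dphi = dirac, by central differences
  h <- 1e-5
  num_deriv <- (heaviside(x + h) - heaviside(x - h)) / (2 * h)
  expect_equal(num_deriv, dirac(x), tolerance = 1e-6)
})

test_that("discrete Gaussian kernel is normalized, radial and correctly valued", {
  for (s in c(0.7, 3, 8)) {
    k <- gaussian_kernel(s)
    expect_equal(sum(k$k2d), 1, tolerance = 1e-12)
    expect_equal(k$radius, ceiling(4 * s))
    expect_identical(k$k2d, t(k$k2d))                     # 90-degree rotation
    expect_identical(k$k2d, k$k2d[rev(seq_len(nrow(k$k2d))), ])
  }
  # center entry of the truncated, renormalized kernel
  k3 <- gaussian_kernel(3)
  d <- -k3$radius:k3$radius
  g <- exp(-d^2 / 18)
  expect_equal(k3$k2d[k3$radius + 1, k3$radius + 1], (1 / sum(g))^2,
               tolerance = 1e-6)
  expect_error(gaussian_kernel(0), "positive")
})

test_that("local means recover constants and match the double-sum oracle", {
  kern <- gaussian_kernel(1.5)
  # constant image, unit bias: both region constants equal the constant
  I <- matrix(0.37, 12, 12)
  b1 <- matrix(1, 12, 12)
  phi <- matrix(rep(c(-3, 3), each = 72), 12, 12)
  cm <- update_local_means(I, b1, phi, kern)
  expect_equal(cm$c1, 0.37, tolerance = 1e-9)
  expect_equal(cm$c2, 0.37, tolerance = 1e-9)
  # crisp two-region piecewise-constant image: constants hit region values
  I2 <- matrix(0.2, 20, 20); I2[6:15, 6:15] <- 0.8
  phi2 <- matrix(1e8, 20, 20); phi2[6:15, 6:15] <- -1e8
  cm2 <- update_local_means(I2, matrix(1, 20, 20), phi2, kern)
  expect_equal(cm2$c1, 0.8, tolerance = 1e-6)
  expect_equal(cm2$c2, 0.2, tolerance = 1e-6)
  # random input against the explicit double-sum ratio oracle
  I3 <- withr::with_seed(11, matrix(runif(256), 16))
  b3 <- withr::with_seed(12, matrix(runif(256, 0.7, 1.3), 16))
  phi3 <- withr::with_seed(13, matrix(rnorm(256, sd = 2), 16))
  cm3 <- update_local_means(I3, b3, phi3, kern)
  H3 <- heaviside(phi3)
  expect_equal(cm3$c1, oracle_region_constant(I3, b3, 1 - H3, kern$k2d),
               tolerance = 1e-8)
  expect_equal(cm3$c2, oracle_region_constant(I3, b3, H3, kern$k2d),
               tolerance = 1e-8)
})

test_that("with unit bias and a huge kernel the constants reduce to region means", {
  # two-phase piecewise-constant limit
  I <- matrix(0.25, 24, 24); I[7:18, 7:18] <- 0.75
  phi <- matrix(1e8, 24, 24); phi[7:18, 7:18] <- -1e8
  b <- matrix(1, 24, 24)
  kern <- gaussian_kernel(40) # > image diagonal (~34)
  cm <- update_local_means(I, b, phi, kern)
  expect_equal(cm$c1, mean(I[phi < 0]), tolerance = 1e-6)
  expect_equal(cm$c2, mean(I[phi > 0]), tolerance = 1e-6)
})

test_that("bias update is exact on an unbiased model and linear in the image", {
  kern <- gaussian_kernel(2)
  # effectively crisp regions: the numerator = denominator identity needs
  # M^2 = M and M1 * M2 = 0
  phi <- matrix(rep(c(-1e8, 1e8), each = 128), 16, 16)
  H <- heaviside(phi)
  c1 <- 0.7; c2 <- 0.3
  I <- c1 * (1 - H) + c2 * H
  b <- update_bias(I, phi, c1, c2, kern)
  expect_equal(b, matrix(1, 16, 16), tolerance = 1e-6)
  # scaling the image scales the returned field (constants held fixed)
  b2 <- update_bias(2 * I, phi, c1, c2, kern)
  expect_equal(b2, 2 * b, tolerance = 1e-9)
})

test_that("alternating mean/bias updates at the true contour recover the bias field", {
  ph <- make_phantom(seed = 42)
  phi <- init_levelset(phantom_mask(ph))$phi0
  phi <- phi * 1e6 # effectively crisp regions
  kern <- gaussian_kernel(min(dim(ph$image)) / 6)
  b <- matrix(1, nrow(ph$image), ncol(ph$image))
  for (i in 1:5) {
    cm <- update_local_means(ph$image, b, phi, kern)
    b <- update_bias(ph$image, phi, cm$c1, cm$c2, kern)
  }
  expect_gte(bias_recovery_score(b, ph$bias), 0.9)
})

test_that("data forces are nonnegative, match the double-sum oracle, and are scale-invariant", {
  kern <- gaussian_kernel(1.2)
  I <- withr::with_seed(5, matrix(runif(256), 16))
  b <- withr::with_seed(6, matrix(runif(256, 0.6, 1.4), 16))
  ef <- data_forces(I, b, c1 = 0.7, c2 = 0.25, kern)
  expect_true(all(ef$e1 >= -1e-9))
  expect_true(all(ef$e2 >= -1e-9))
  expect_equal(ef$e1, oracle_data_force(I, b, 0.7, kern$k2d), tolerance = 1e-8)
  expect_equal(ef$e2, oracle_data_force(I, b, 0.25, kern$k2d), tolerance = 1e-8)
  # perfect fit: I = c_i with unit bias has zero residual in the interior
  Ic <- matrix(0.7, 16, 16)
  b1 <- matrix(1, 16, 16)
  ef2 <- data_forces(Ic, b1, c1 = 0.7, c2 = 0.25, kern)
  inner <- ef2$e1[6:11, 6:11]
  expect_equal(inner, matrix(0, 6, 6), tolerance = 1e-12)
  # at I = 0 with unit bias, the force reduces to c_i^2 * 1_K
  I0 <- matrix(0, 16, 16)
  ef3 <- data_forces(I0, b1, c1 = 0.7, c2 = 0.25, kern)
  oneK <- kfls:::one_K(c(16L, 16L), kern)
  expect_equal(ef3$e1, 0.7^2 * oneK, tolerance = 1e-12)
  expect_true(all(abs(oneK[6:11, 6:11] - 1) < 1e-12)) # interior
  expect_true(all(oneK[1, ] < 1))                     # borders
  # bias/constant scale split leaves the forces unchanged
  s <- 1.7
  ef4 <- data_forces(I, s * b, c1 = 0.7 / s, c2 = 0.25 / s, kern)
  expect_equal(ef4$e1, ef$e1, tolerance = 1e-9)
  expect_equal(ef4$e2 - ef4$e1, ef$e2 - ef$e1, tolerance = 1e-9)
})

test_that("curvature vanishes on ramps, negates with phi, and matches 1/r on a disk", {
  ramp <- matrix(seq_len(32), 32, 32)
  k <- curvature(ramp)
  expect_equal(k[3:30, 3:30], matrix(0, 28, 28), tolerance = 1e-9)
  phi <- withr::with_seed(9, matrix(rnorm(400), 20))
  expect_equal(curvature(-phi), -curvature(phi), tolerance = 1e-9)
  # signed distance to a circle of radius r: curvature ~ 1/r at the zero set
  r <- 15
  cc <- 32.5
  d <- sqrt(outer((seq_len(64) - cc)^2, (seq_len(64) - cc)^2, "+")) - r
  kap <- curvature(d)
  at_zero <- abs(d) < 0.5
  expect_equal(mean(kap[at_zero]), 1 / r, tolerance = 0.1) # within 10%
})

test_that("a step with balanced forces leaves a flat far-field phi unchanged", {
  I <- matrix(0.5, 24, 24) # constant image: e1 = e2 everywhere
  st <- levelset_state(matrix(5, 24, 24)) # flat, far from the zero set
  params <- evolution_params(derive_params(2), sigma_K = 2)
  st2 <- evolve_step(st, I, params)
  expect_lt(max(abs(st2$phi[3:22, 3:22] - 5)), 1e-6)
})

test_that("evolution steps are deterministic and descend the fitting energy", {
  ph <- make_phantom(noise_sigma = 0, seed = 17)
  phi0 <- init_levelset(phantom_mask(ph))
  params <- evolution_params(derive_params(estimate_tau(phi0)))
  params$sigma_K <- kfls:::resolve_sigma_K(params, dim(ph$image))
  kern <- gaussian_kernel(params$sigma_K)
  st <- levelset_state(phi0)
  E <- fitting_energy(st, ph$image, params, kern)
  for (i in 1:5) {
    st <- evolve_step(st, ph$image, params, kern)
    E2 <- fitting_energy(st, ph$image, params, kern)
    expect_lte(E2, E + 1e-7)
    E <- E2
  }
  # determinism: same inputs, bit-identical state
  sa <- evolve_step(levelset_state(phi0), ph$image, params, kern)
  sb <- evolve_step(levelset_state(phi0), ph$image, params, kern)
  expect_identical(sa$phi, sb$phi)
  expect_identical(sa$b, sb$b)
})

test_that("the evolution honors its iteration budget and stopping contract", {
  ph <- make_phantom(shape = c(48, 48), seed = 2)
  phi0 <- init_levelset(phantom_mask(ph))
  params <- evolution_params(derive_params(estimate_tau(phi0)),
                             max_iter = 1, stop_tol = 1)
  res <- run_evolution(ph$image, phi0, params)
  expect_equal(res$iterations, 1L)
  expect_error(run_evolution(ph$image, matrix(1, 48, 48)), "both signs")
})

test_that("long evolutions remain finite across phantom seeds", {
  for (s in 1:20) {
    ph <- make_phantom(shape = c(32, 32), seed = 200 + s)
    phi0 <- init_levelset(phantom_mask(ph))
    params <- evolution_params(derive_params(estimate_tau(phi0)),
                               max_iter = 1000, stop_tol = 0)
    res <- run_evolution(ph$image, phi0, params)
    expect_true(all(is.finite(res$phi)))
    expect_true(all(is.finite(res$b)))
    expect_equal(res$iterations, 1000L)
  }
})
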