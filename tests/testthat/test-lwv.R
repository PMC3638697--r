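test_that("spectral peak finding refines Gaussians to sub-cell precision", {
  xi <- seq(-400, 400, by = 20)
  gauss2d <- function(c1, c2, w, amp = 1) {
    amp * exp(-outer((xi - c1)^2, (xi - c2)^2, "+") / (2 * w^2))
  }
  sigma <- 5e-3

  # peak exactly on a node
  sp <- synthetic_spectrum(gauss2d(100, -200, 60) + 0i, xi, xi, sigma)
  pk <- spectral_peak(sp)
  expect_equal(pk$xi, c(100, -200))
  expect_equal(pk$offset, c(0, 0))

  # peak between nodes: log-quadratic is exact for a Gaussian profile
  for (ctr in list(c(107.3, -192.6), c(-53.9, 246.1))) {
    pk <- spectral_peak(synthetic_spectrum(gauss2d(ctr[1], ctr[2], 60) + 0i,
                                           xi, xi, sigma))
    expect_lt(max(abs(pk$xi - ctr)), 0.02 * 20)
  }

  # two peaks 2:1 -> the stronger one wins (checked against brute force)
  m <- gauss2d(140, 140, 50, 2) + gauss2d(-180, 60, 50, 1)
  pk <- spectral_peak(synthetic_spectrum(m + 0i, xi, xi, sigma))
  brute <- which(m == max(m), arr.ind = TRUE)
  expect_equal(pk$node, as.integer(brute[1, ]))
  expect_lt(max(abs(pk$xi - c(140, 140))), 1)

  # exact tie -> smallest |xi| preferred
  m2 <- gauss2d(100, 0, 40) + gauss2d(300, 0, 40)
  pk2 <- spectral_peak(synthetic_spectrum(m2 + 0i, xi, xi, sigma))
  expect_equal(pk2$xi[1], 100, tolerance = 1)

  # masking everything is an error
  expect_error(spectral_peak(synthetic_spectrum(m + 0i, xi, xi, sigma),
                             min_xi_norm = 1e6), "masked")
})

test_that("local wave vectors are recovered to <1% across wavelengths", {
  for (wl in c(8, 16, 32)) {
    for (th in c(0.3, 2.0)) {
      pf <- plane_field(nx = 96, wavelength_px = wl, direction = th)
      sigma <- wl * 1e-3       # one wavelength
      b <- local_wave_vector(pf$field, pf$center, sigma)
      expect_lt(relerr(b, pf$beta), 0.01)
    }
  }
})

test_that("wave-vector estimation is amplitude invariant and rotation equivariant", {
  pf <- plane_field(nx = 64, wavelength_px = 12, direction = 0.6)
  sigma <- 6e-3
  b <- local_wave_vector(pf$field, pf$center, sigma)

  fs <- wave_field((0.3 - 2i) * pf$field$values, pf$grid, 250)
  expect_equal(as.numeric(local_wave_vector(fs, pf$center, sigma)),
               as.numeric(b), tolerance = 1e-12)

  # rotating the wave by 90 degrees rotates the estimate identically
  pf90 <- plane_field(nx = 64, wavelength_px = 12, direction = 0.6 + pi / 2)
  b90 <- local_wave_vector(pf90$field, pf90$center, sigma)
  expect_equal(as.numeric(b90), c(-b[2], b[1]), tolerance = 1e-3 * sqrt(sum(b^2)))
})

test_that("the stronger component of a two-wave mixture wins", {
  g <- mre_grid(96, 96, 1e-3)
  omega <- 2 * pi * 250
  b1 <- (2 * pi / (omega * 0.012)) * c(cos(0.4), sin(0.4))
  b2 <- (2 * pi / (omega * 0.015)) * c(cos(2.2), sin(2.2))
  ctr <- c(0.0475, 0.0475)
  f <- make_wave_field(list(wave_component(2, b1, anchor = ctr),
                            wave_component(1, b2, anchor = ctr)), g, omega)
  b <- local_wave_vector(f, ctr, sigma = 0.012)
  expect_lt(relerr(b, b1), 0.02)
})

test_that("wave-vector maps are homogeneous and samplewise independent", {
  pf <- plane_field(nx = 72, wavelength_px = 10, direction = 1.1)
  sigma <- 5e-3
  vm <- wave_vector_map(pf$field, spacing = 6, sigma = sigma)
  bn <- sqrt(vm$beta_x^2 + vm$beta_y^2)
  expect_gt(nrow(vm), 10)
  expect_lt((max(bn) - min(bn)) / mean(bn), 0.01)
  expect_lt(max(abs(vm$beta_x - pf$beta[1])), 0.01 * sqrt(sum(pf$beta^2)))

  # coarser sampling is a strict subset of finer sampling
  vm1 <- wave_vector_map(pf$field, spacing = 2, sigma = sigma)
  key <- function(d) paste(round(d$x_m, 9), round(d$y_m, 9))
  common <- match(key(vm), key(vm1))
  expect_false(anyNA(common))
  expect_equal(vm1$beta_x[common], vm$beta_x, tolerance = 1e-12)
  expect_equal(vm1$beta_y[common], vm$beta_y, tolerance = 1e-12)
})

test_that("a two-region field shows the sqrt(G' ratio) slowness contrast", {
  cfg <- simulation_config(
    nx = 128, ny = 64, noise_to_signal = 0, h = 1.2e-3,
    regions = list(sim_region(Gp = 14400, Gpp = 0, x_range = c(0, 0.5)),
                   sim_region(Gp = 3600, Gpp = 0, x_range = c(0.5, 1))))
  sim <- simulate_experiment(cfg)
  sigma <- 0.75 * 2 * pi / (2 * pi * 250 * sqrt(1000 / 14400))
  vm <- wave_vector_map(sim$field, spacing = 8, sigma = sigma)
  xs <- grid_x(sim$field$grid)
  mid <- mean(range(xs))
  left <- vm$x_m < mid - 2 * sigma
  right <- vm$x_m > mid + 2 * sigma
  bn <- sqrt(vm$beta_x^2 + vm$beta_y^2)
  expect_gt(sum(left), 3); expect_gt(sum(right), 3)
  expect_equal(mean(bn[right]) / mean(bn[left]), 2, tolerance = 0.05)
})

test_that("window-size suggestion follows the dominant wavelength", {
  pf <- plane_field(nx = 64, wavelength_px = 16, direction = 0.25)
  lam <- 16e-3
  s1 <- suggest_sigma(pf$field, factor = 1)
  expect_equal(s1, lam, tolerance = 2 * pi / (64e-3) / (2 * pi / lam))
  expect_equal(suggest_sigma(pf$field, factor = 0.5), s1 / 2, tolerance = 1e-12)
  expect_warning(suggest_sigma(pf$field, factor = 0.3), "outside")

  set.seed(9)
  noise <- wave_field(matrix(complex(real = rnorm(4096), imaginary = rnorm(4096)),
                             64), mre_grid(64, 64, 1e-3), 250)
  expect_error(suggest_sigma(noise), "degenerate")
})
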