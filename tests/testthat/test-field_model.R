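test_that("make_wave_field evaluates the multiple-wave form pointwise", {
  g <- mre_grid(32, 32, 1e-3)
  omega <- 2 * pi * 250
  beta <- c(0, 40) / omega   # pure-phase wave along y

  f <- make_wave_field(list(wave_component(1, beta)), g, omega)
  expect_equal(max(abs(Mod(f$values) - 1)), 0, tolerance = 1e-12)

  # a zero-amplitude term is inert
  f2 <- make_wave_field(list(wave_component(2 - 1i, beta, anchor = c(0.01, 0)),
                             wave_component(0, c(1, 2) * 0.1)), g, omega)
  f1 <- make_wave_field(list(wave_component(2 - 1i, beta, anchor = c(0.01, 0))),
                        g, omega)
  expect_identical(f2$values, f1$values)

  # collinear attenuation: |u| matches an independently evaluated scalar
  # exponential along the propagation direction
  a0 <- 0.02
  bdir <- c(1, 0)
  beta2 <- 0.25 * bdir
  cmp <- wave_component(1, beta2, alpha = a0 * bdir, anchor = c(0, 0))
  f3 <- make_wave_field(list(cmp), g, omega)
  xs <- grid_x(g)
  expect_equal(Mod(f3$values[, 1]), exp(omega * a0 * xs), tolerance = 1e-12)

  expect_error(make_wave_field(list(), g, omega), "at least one")
  expect_error(wave_component(NaN, beta), "finite")
  expect_error(wave_component(1, c(0, 0)), "nonzero")
})

test_that("field synthesis is linear in the component list", {
  g <- mre_grid(24, 24, 1e-3)
  omega <- 2 * pi * 250
  set.seed(11)
  comps <- lapply(1:4, function(i) {
    wave_component(complex(real = rnorm(1), imaginary = rnorm(1)),
                   beta = 0.3 * c(cos(i), sin(i)),
                   alpha = 0.01 * c(rnorm(1), rnorm(1)),
                   anchor = 0.01 * c(runif(1), runif(1)))
  })
  whole <- make_wave_field(comps, g, omega)$values
  parts <- Reduce(`+`, lapply(comps, function(cm)
    make_wave_field(list(cm), g, omega)$values))
  expect_lt(max(Mod(whole - parts)), 1e-12 * max(Mod(whole)))
})

test_that("quadrature pair assembly matches u = phi - i psi", {
  g <- mre_grid(16, 16, 1e-3)
  xs <- grid_x(g)
  k <- 300
  phi <- matrix(cos(k * xs), 16, 16)
  psi <- matrix(-sin(k * xs), 16, 16)
  f <- field_from_quadrature(phi, psi, g, 100)
  expect_equal(f$values, matrix(exp(1i * k * xs), 16, 16), tolerance = 1e-12)

  set.seed(2)
  phi <- matrix(rnorm(256), 16); psi <- matrix(rnorm(256), 16)
  f2 <- field_from_quadrature(phi, psi, g, 100)
  expect_identical(Re(f2$values), phi)
  expect_identical(Im(f2$values), -psi)
  f3 <- field_from_quadrature(phi, 0 * psi, g, 100)
  expect_true(all(Im(f3$values) == 0))
  expect_error(field_from_quadrature(phi, psi[, 1:8], g, 100), "same shape")
})

test_that("snapshot combination extracts the first temporal harmonic exactly", {
  g <- mre_grid(16, 16, 1e-3)
  set.seed(5)
  u <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16)
  f <- wave_field(u, g, 250)

  # rendering then combining is the identity, for several N
  for (n in c(4, 8, 12)) {
    back <- combine_snapshots(render_snapshots(f, n))
    expect_equal(back$values, u, tolerance = 1e-12)
  }

  # opposite acquisition convention round trips with the matching sign
  back2 <- combine_snapshots(render_snapshots(f, 8, harmonic_sign = -1),
                             harmonic_sign = -1)
  expect_equal(back2$values, u, tolerance = 1e-12)

  # zero and constant (DC) stacks have no first harmonic
  z <- lapply(1:8, function(k) matrix(0, 16, 16))
  expect_equal(max(Mod(combine_snapshots(snapshot_stack(z, g, 250))$values)), 0)
  dc <- lapply(1:8, function(k) matrix(3.7, 16, 16))
  expect_lt(max(Mod(combine_snapshots(snapshot_stack(dc, g, 250))$values)), 1e-12)

  expect_error(snapshot_stack(z[1], g, 250), "at least 2")
})

test_that("gaussian noise honors the S/N definition and the seed", {
  pf <- plane_field(nx = 256, ny = 256, wavelength_px = 12)
  f <- pf$field

  # vanishing noise
  f9 <- add_gaussian_noise(f, snr = 1e9, seed = 1)
  expect_lt(max(Mod(f9$values - f$values)),
            1e-6 * sqrt(mean(Mod(f$values)^2)))

  # determinism / seed sensitivity
  a <- add_gaussian_noise(f, snr = 0.1, seed = 42)
  b <- add_gaussian_noise(f, snr = 0.1, seed = 42)
  d <- add_gaussian_noise(f, snr = 0.1, seed = 43)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, d$values))

  # realized noise RMS is 10x the signal RMS at snr = 0.1, within 2%
  noise <- a$values - f$values
  ratio <- sqrt(mean(Mod(f$values)^2)) / sqrt(mean(Mod(noise)^2))
  expect_equal(ratio, 0.1, tolerance = 0.02)

  # adding noise must not disturb the caller's RNG stream
  set.seed(7); r1 <- rnorm(3)
  set.seed(7); invisible(add_gaussian_noise(f, 1, seed = 9)); r2 <- rnorm(3)
  expect_identical(r1, r2)

  expect_error(add_gaussian_noise(f, snr = 0), "positive")
})

test_that("simulated experiments carry dispersion-exact ground truth", {
  # noiseless limit reproduces the clean field
  cfg <- simulation_config(nx = 32, ny = 32, noise_to_signal = 0)
  sim <- simulate_experiment(cfg)
  expect_identical(sim$field$values, sim$clean$values)

  # ground-truth vectors satisfy rho + (G' + iG'')(alpha + i beta)^2 = 0
  al <- c(sim$truth$alpha_x[1, 1], sim$truth$alpha_y[1, 1])
  be <- c(sim$truth$beta_x[1, 1], sim$truth$beta_y[1, 1])
  gstar <- sim$truth$Gp[1, 1] + 1i * sim$truth$Gpp[1, 1]
  z <- sum((al + 1i * be) * (al + 1i * be))
  expect_lt(Mod(cfg$rho + gstar * z), 1e-9 * cfg$rho)

  # |alpha| / |beta| matches the configured ratio
  expect_equal(sqrt(sum(al^2)) / sqrt(sum(be^2)), 0.1, tolerance = 1e-10)

  # two lossless regions: |beta| scales as 1 / sqrt(G')
  cfg2 <- simulation_config(
    nx = 32, ny = 32, noise_to_signal = 0,
    regions = list(sim_region(Gp = 14400, Gpp = 0, x_range = c(0, 0.5)),
                   sim_region(Gp = 3600, Gpp = 0, x_range = c(0.5, 1))))
  s2 <- simulate_experiment(cfg2)
  b1 <- sqrt(s2$truth$beta_x[1, 1]^2 + s2$truth$beta_y[1, 1]^2)
  b2 <- sqrt(s2$truth$beta_x[32, 1]^2 + s2$truth$beta_y[32, 1]^2)
  expect_equal(b2 / b1, sqrt(14400 / 3600), tolerance = 1e-12)

  # noise is reproducible through the config seed
  cfgn <- simulation_config(nx = 32, ny = 32, seed = 3)
  expect_identical(simulate_experiment(cfgn)$field$values,
                   simulate_experiment(cfgn)$field$values)
})
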