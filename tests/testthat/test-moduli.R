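test_that("the dispersion relation maps vectors to the expected moduli", {
  # lossless wave of 14.4 kPa stiffness: |beta| = sqrt(rho / G')
  b <- sqrt(1000 / 14400)
  g <- moduli_from_vectors(c(0, 0), b * c(1, 1) / sqrt(2), rho = 1000)
  expect_equal(g[["Gp"]], 14400, tolerance = 1e-12)
  expect_equal(g[["Gpp"]], 0)

  # degenerate direction: |alpha| = |beta|, alpha perpendicular to beta
  expect_error(moduli_from_vectors(c(0.1, 0), c(0, 0.1)), "degenerate")
  expect_error(moduli_from_vectors(c(0, 0), c(0, 0)), "nonzero")

  # any random pair satisfies rho + (G' + iG'')(alpha + i beta)^2 = 0
  set.seed(31)
  for (i in 1:50) {
    al <- rnorm(2, sd = 0.05); be <- rnorm(2, sd = 0.3)
    g <- moduli_from_vectors(al, be, rho = 1000)
    z <- sum((al + 1i * be) * (al + 1i * be))
    expect_lt(Mod(1000 + (g[["Gp"]] + 1i * g[["Gpp"]]) * z), 1e-12 * 1000)
    # sign law: G'' and alpha.beta share their sign
    expect_equal(sign(g[["Gpp"]]), sign(sum(al * be)))
  }
})

test_that("the lossless approximation tracks the full relation for weak attenuation", {
  expect_equal(storage_modulus_approx(sqrt(1000 / 14400) * c(0, 1), 1000),
               14400, tolerance = 1e-12)
  expect_equal(storage_modulus_approx(2 * sqrt(1000 / 14400) * c(0, 1), 1000),
               14400 / 4, tolerance = 1e-12)
  expect_error(storage_modulus_approx(c(0, 0)), "positive")

  set.seed(8)
  for (i in 1:20) {
    Gp <- runif(1, 2e3, 5e4); Gpp <- runif(1, 0.01, 0.05) * Gp
    r <- runif(1, 0.02, 0.1)
    ab <- vectors_from_moduli(Gp, Gpp, 1000,
                              angle_alpha_beta = alpha_angle_for_ratio(Gp, Gpp, 1000, r))
    expect_lt(abs(storage_modulus_approx(ab$beta, 1000) - Gp) / Gp, 0.01)
  }
})

test_that("moduli -> vectors -> moduli is the identity on the feasible set", {
  # lossless limit
  ab <- vectors_from_moduli(14400, 0, 1000, beta_dir = c(0, 1))
  expect_equal(ab$alpha, c(0, 0))
  expect_equal(sqrt(sum(ab$beta^2)), sqrt(1000 / 14400), tolerance = 1e-12)

  # collinear alpha and beta
  ab2 <- vectors_from_moduli(14400, 690, 1000, angle_alpha_beta = 0)
  g2 <- moduli_from_vectors(ab2$alpha, ab2$beta, 1000)
  expect_equal(unname(g2), c(14400, 690), tolerance = 1e-9)

  # infeasible angle names the constraint
  expect_error(vectors_from_moduli(14400, 690, 1000, angle_alpha_beta = 2.5),
               "cos\\(angle\\)")

  # 1000 random feasible configurations round trip to 1e-9
  set.seed(77)
  worst <- 0
  for (i in 1:1000) {
    Gp <- runif(1, 5e2, 1e5)
    Gpp <- runif(1, 0, 0.5) * Gp
    th <- runif(1, 0, 2 * pi)
    ang <- if (Gpp > 0) runif(1, 0.01, pi / 2 - 0.01) else runif(1, 0, pi)
    ab <- vectors_from_moduli(Gp, Gpp, 1000, c(cos(th), sin(th)), ang)
    g <- moduli_from_vectors(ab$alpha, ab$beta, 1000)
    worst <- max(worst, abs(g[["Gp"]] - Gp) / Gp,
                 if (Gpp > 0) abs(g[["Gpp"]] - Gpp) / Gpp else 0)
  }
  expect_lt(worst, 1e-9)
})

test_that("moduli maps apply the low-slowness mask and recover region truth", {
  # uniform |beta|: nothing masked
  vm <- structure(data.frame(x_m = 1:5 * 1e-3, y_m = 1:5 * 1e-3,
                             beta_x = 0.2, beta_y = 0.1,
                             xi_x = NA, xi_y = NA, peak_mag = 1,
                             clipped = FALSE, low_contrast = FALSE),
                  class = c("vector_field_map", "data.frame"))
  mm <- moduli_map(vm, rho = 1000, low_beta_cutoff = 0.9)
  expect_true(all(mm$valid))
  expect_equal(mm$Gp_Pa, rep(1000 / 0.05, 5), tolerance = 1e-12)

  # one zero-slowness point is masked with a reason, the rest computed
  vm$beta_x[3] <- 0; vm$beta_y[3] <- 0
  mm2 <- moduli_map(vm, rho = 1000)
  expect_false(mm2$valid[3])
  expect_equal(mm2$reason[3], "low-beta")
  expect_true(all(mm2$valid[-3]))

  # boundary-clipped points are masked too
  vm$clipped[1] <- TRUE
  mm3 <- moduli_map(vm, rho = 1000)
  expect_equal(mm3$reason[1], "boundary")

  expect_error(moduli_map(vm[0, ]), "empty")

  # noiseless two-region field: per-region mean G' within 1% of truth
  cfg <- simulation_config(
    nx = 128, ny = 64, h = 1.2e-3, noise_to_signal = 0,
    regions = list(sim_region(Gp = 14400, Gpp = 0, x_range = c(0, 0.5)),
                   sim_region(Gp = 3600, Gpp = 0, x_range = c(0.5, 1))))
  sim <- simulate_experiment(cfg)
  sigma <- 0.75 * 2 * pi / (2 * pi * 250 * sqrt(1000 / 14400))
  vmap <- wave_vector_map(sim$field, spacing = 8, sigma = sigma)
  mmap <- moduli_map(vmap, rho = 1000)
  xs <- grid_x(sim$field$grid); mid <- mean(range(xs))
  lm_ <- mmap$valid & mmap$x_m < mid - 2 * sigma
  rm_ <- mmap$valid & mmap$x_m > mid + 2 * sigma
  expect_equal(mean(mmap$Gp_Pa[lm_]), 14400, tolerance = 0.01)
  expect_equal(mean(mmap$Gp_Pa[rm_]), 3600, tolerance = 0.01)
})

test_that("ROI statistics use the population standard deviation", {
  mk <- function(gp) {
    structure(data.frame(x_m = seq_along(gp) * 1e-3, y_m = 1e-3,
                         Gp_Pa = gp, Gpp_Pa = NA_real_,
                         valid = TRUE, reason = ""),
              class = c("moduli_map", "data.frame"))
  }
  roi <- list(all = list(xlim = c(0, 1), ylim = c(0, 1)))
  st <- roi_stats(mk(rep(5, 4)), roi)
  expect_equal(st$mean_Pa, 5); expect_equal(st$sd_Pa, 0); expect_equal(st$n, 4)

  st2 <- roi_stats(mk(c(2, 8)), roi)
  expect_equal(st2$mean_Pa, 5)
  expect_equal(st2$sd_Pa, 3)   # |a - b| / 2, divide-by-N convention

  expect_error(roi_stats(mk(c(2, 8)),
                         list(far = list(xlim = c(5, 6), ylim = c(5, 6)))),
               "no unmasked")
})
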