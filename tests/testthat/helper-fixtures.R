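# Shared fixtures: all synthetic, built in code.

# single-wave field with slowness magnitude set by wavelength (in pixels)
plane_field <- function(nx = 64, ny = nx, h = 1e-3, frequency_hz = 250,
                        wavelength_px = 10, direction = 0.3,
                        alpha = c(0, 0), amplitude = 1, anchor = NULL) {
  g <- mre_grid(nx, ny, h)
  omega <- 2 * pi * frequency_hz
  bnorm <- 2 * pi / (omega * wavelength_px * h)
  beta <- bnorm * c(cos(direction), sin(direction))
  if (is.null(anchor)) anchor <- c(mean(range(grid_x(g))), mean(range(grid_y(g))))
  cmp <- wave_component(amplitude, beta, alpha, anchor)
  list(field = make_wave_field(list(cmp), g, omega),
       component = cmp, beta = beta, omega = omega, grid = g,
       center = anchor)
}

# attenuated wave whose (alpha, beta) realize given moduli exactly
moduli_field <- function(nx = 96, ny = nx, h = 1e-3, frequency_hz = 250,
                         Gp = 14400, Gpp = 690, rho = 1000, ratio = 0.1,
                         beta_angle = pi / 4, amplitude = 1) {
  g <- mre_grid(nx, ny, h)
  omega <- 2 * pi * frequency_hz
  ang <- if (Gpp > 0) alpha_angle_for_ratio(Gp, Gpp, rho, ratio) else NULL
  ab <- vectors_from_moduli(Gp, Gpp, rho,
                            c(cos(beta_angle), sin(beta_angle)), ang)
  anchor <- c(mean(range(grid_x(g))), mean(range(grid_y(g))))
  cmp <- wave_component(amplitude, ab$beta, ab$alpha, anchor)
  list(field = make_wave_field(list(cmp), g, omega),
       component = cmp, alpha = ab$alpha, beta = ab$beta,
       omega = omega, grid = g, center = anchor, rho = rho)
}

# hand-built spectrum object for fit tests (documented structure)
synthetic_spectrum <- function(values, xi_x, xi_y, sigma, omega = 2 * pi * 250) {
  structure(list(values = values, xi_x = xi_x, xi_y = xi_y,
                 dxi = xi_x[2] - xi_x[1], p = c(0, 0), sigma = sigma,
                 omega = omega, h = NA_real_, kernel_centered = TRUE,
                 clipped = FALSE, window_mass = 2 * pi * sigma^2),
            class = "fbi_spectrum")
}

relerr <- function(est, truth) {
  sqrt(sum((est - truth)^2)) / sqrt(sum(truth^2))
}
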