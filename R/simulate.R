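#' One homogeneous region of a simulated phantom
#'
#' Describes a vertical slab of the simulated field (a fraction of the x
#' extent) with its own true moduli and wave geometry.  The slab's
#' attenuated plane wave is derived from `(G', G'')` through
#' [vectors_from_moduli()], so the ground truth satisfies the dispersion
#' relation exactly.
#'
#' @param Gp,Gpp True storage and loss moduli in Pa.
#' @param beta_angle Propagation direction of `beta`, radians
#'   counterclockwise from the x axis (default 45 degrees, upper-right).
#' @param alpha_angle Angle from `beta` to `alpha` in radians; `NULL`
#'   (default) picks the angle giving `|alpha| = alpha_beta_ratio * |beta|`.
#' @param alpha_beta_ratio Target `|alpha|/|beta|` when `alpha_angle` is
#'   `NULL` (default 0.1, weak attenuation).
#' @param amplitude Complex amplitude at the region's anchor.
#' @param x_range Fractions of the grid x extent covered by the region.
#' @return A list of class `sim_region`.
#' @export
sim_region <- function(Gp = 14400, Gpp = 690, beta_angle = pi / 4,
                       alpha_angle = NULL, alpha_beta_ratio = 0.1,
                       amplitude = 1, x_range = c(0, 1)) {
  stopifnot(Gp > 0, Gpp >= 0, length(x_range) == 2L, x_range[1] < x_range[2])
  structure(list(Gp = Gp, Gpp = Gpp, beta_angle = beta_angle,
                 alpha_angle = alpha_angle,
                 alpha_beta_ratio = alpha_beta_ratio,
                 amplitude = amplitude + 0i, x_range = x_range),
            class = "sim_region")
}

#' Configuration of a synthetic MRE experiment
#'
#' Defines the study conditions of the simulated phantom: a bounded
#' rectangular slice, one attenuated plane wave per region, and additive
#' complex Gaussian white noise.  Defaults emulate a gel phantom imaged
#' at micro-MRE resolution: 96 x 96 pixels of 1.2 mm at 250 Hz — about
#' 7.6 wavelengths across the field for the default 14.4 kPa stiffness —
#' true `G' = 14.4` kPa and `G'' = 0.69` kPa, density 1000 kg/m^3, and a
#' noise-to-signal RMS ratio just below 0.1.
#'
#' @param nx,ny,h Grid size (pixels) and pixel spacing (meters).
#' @param frequency_hz Vibration frequency in Hz.
#' @param rho Density in kg/m^3.
#' @param regions List of [sim_region()] definitions; their `x_range`
#'   fractions must cover the grid without overlap.
#' @param noise_to_signal Ratio `RMS(|noise|) / RMS(|u_clean|)`
#'   (default 0.095); set to `0` for a noiseless experiment.
#' @param seed Integer RNG seed for the noise.
#' @param rois Named list of rectangular regions of interest in meters
#'   (each `list(xlim=, ylim=)`); `NULL` installs the defaults `center`
#'   (central third in x and y) and `right` (right third in x, full y).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(nx = 96, ny = 96, h = 1.2e-3,
                              frequency_hz = 250, rho = 1000,
                              regions = list(sim_region()),
                              noise_to_signal = 0.095, seed = 1,
                              rois = NULL) {
  stopifnot(rho > 0, noise_to_signal >= 0, length(regions) >= 1L)
  grid <- mre_grid(nx, ny, h)
  if (is.null(rois)) {
    lx <- (nx - 1) * h; ly <- (ny - 1) * h
    rois <- list(
      center = list(xlim = c(lx / 3, 2 * lx / 3), ylim = c(ly / 3, 2 * ly / 3)),
      right  = list(xlim = c(2 * lx / 3, lx),     ylim = c(0, ly)))
  }
  for (r in rois) {
    if (r$xlim[1] < grid$origin[1] - h / 2 ||
        r$xlim[2] > grid$origin[1] + (nx - 1) * h + h / 2 ||
        r$ylim[1] < grid$origin[2] - h / 2 ||
        r$ylim[2] > grid$origin[2] + (ny - 1) * h + h / 2)
      stop("ROI lies outside the grid")
  }
  structure(list(grid = grid, frequency_hz = frequency_hz, rho = rho,
                 regions = regions, noise_to_signal = noise_to_signal,
                 seed = seed, rois = rois),
            class = "simulation_config")
}

#' Simulate a noisy wave field with known ground truth
#'
#' Builds the noise-free field region by region — each region carries a
#' single attenuated plane wave whose `(alpha, beta)` realize that
#' region's true `(G', G'')` exactly — adds complex Gaussian white noise
#' at the configured noise-to-signal ratio, and returns both fields
#' together with per-pixel ground-truth maps.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mre_simulation` with elements `field` (noisy
#'   [wave_field()]), `clean` (noise-free field), `truth` (list of
#'   per-pixel matrices `alpha_x`, `alpha_y`, `beta_x`, `beta_y`, `Gp`,
#'   `Gpp`), `rois`, `rho` and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$grid
  omega <- 2 * pi * config$frequency_hz
  xs <- grid_x(g); ys <- grid_y(g)
  x0 <- xs[1]; lx <- xs[g$nx] - xs[1]
  anchor <- c(mean(range(xs)), mean(range(ys)))
  values <- matrix(0i, g$nx, g$ny)
  truth <- list(alpha_x = matrix(NA_real_, g$nx, g$ny),
                alpha_y = matrix(NA_real_, g$nx, g$ny),
                beta_x = matrix(NA_real_, g$nx, g$ny),
                beta_y = matrix(NA_real_, g$nx, g$ny),
                Gp = matrix(NA_real_, g$nx, g$ny),
                Gpp = matrix(NA_real_, g$nx, g$ny))
  covered <- rep(FALSE, g$nx)
  for (reg in config$regions) {
    stopifnot(inherits(reg, "sim_region"))
    angle <- reg$alpha_angle
    if (is.null(angle) && reg$Gpp > 0)
      angle <- alpha_angle_for_ratio(reg$Gp, reg$Gpp, config$rho,
                                     reg$alpha_beta_ratio)
    bdir <- c(cos(reg$beta_angle), sin(reg$beta_angle))
    ab <- vectors_from_moduli(reg$Gp, reg$Gpp, config$rho, bdir, angle)
    sel <- xs >= x0 + reg$x_range[1] * lx - g$h / 2 &
           xs <= x0 + reg$x_range[2] * lx + g$h / 2 & !covered
    if (!any(sel)) stop("simulation region covers no pixels")
    covered[sel] <- TRUE
    cmp <- wave_component(reg$amplitude, beta = ab$beta, alpha = ab$alpha,
                          anchor = anchor)
    values[sel, ] <- eval_component(cmp, omega, xs[sel], ys)
    truth$alpha_x[sel, ] <- ab$alpha[1]; truth$alpha_y[sel, ] <- ab$alpha[2]
    truth$beta_x[sel, ] <- ab$beta[1];  truth$beta_y[sel, ] <- ab$beta[2]
    truth$Gp[sel, ] <- reg$Gp;          truth$Gpp[sel, ] <- reg$Gpp
  }
  if (!all(covered)) stop("simulation regions do not cover the grid in x")
  clean <- wave_field(values, g, config$frequency_hz)
  field <- if (config$noise_to_signal > 0) {
    add_gaussian_noise(clean, snr = 1 / config$noise_to_signal,
                       seed = config$seed)
  } else clean
  structure(list(field = field, clean = clean, truth = truth,
                 rois = config$rois, rho = config$rho, config = config),
            class = "mre_simulation")
}

#' @export
print.mre_simulation <- function(x, ...) {
  cat(sprintf("<mre_simulation> %d x %d, f = %g Hz, %d region(s), N/S = %g\n",
              x$field$grid$nx, x$field$grid$ny, x$field$frequency_hz,
              length(x$config$regions), x$config$noise_to_signal))
  invisible(x)
}
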