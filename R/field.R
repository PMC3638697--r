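#' Complex scalar wave field on a metric grid
#'
#' The basic container of the package: the complex displacement image
#' `u(x) = phi(x) - i psi(x)` of a time-harmonic shear wave, sampled at
#' pixel centers, together with the vibration frequency.  `values[i, j]`
#' holds `u` at the pixel with 0-based index `(i-1, j-1)`, so rows index
#' x and columns index y.
#'
#' @param values Complex (or numeric) `nx x ny` matrix of displacements.
#' @param grid An [mre_grid()].
#' @param frequency_hz Vibration frequency f in Hz; the angular frequency
#'   `omega = 2*pi*f` is stored alongside.
#' @return An object of class `wave_field` with elements `values`, `grid`,
#'   `frequency_hz` and `omega`.
#' @export
wave_field <- function(values, grid, frequency_hz) {
  stopifnot(inherits(grid, "mre_grid"), is.matrix(values))
  if (nrow(values) != grid$nx || ncol(values) != grid$ny)
    stop("`values` must be an nx x ny matrix matching the grid")
  if (!is.complex(values)) values <- values + 0i
  if (!all(is.finite(Re(values)) & is.finite(Im(values))))
    stop("wave field values must be finite")
  if (!is.finite(frequency_hz) || frequency_hz <= 0)
    stop("`frequency_hz` must be positive")
  structure(list(values = values, grid = grid,
                 frequency_hz = as.numeric(frequency_hz),
                 omega = 2 * pi * as.numeric(frequency_hz)),
            class = "wave_field")
}

#' @export
print.wave_field <- function(x, ...) {
  cat(sprintf("<wave_field> %d x %d, h = %g m, f = %g Hz, RMS |u| = %.4g\n",
              x$grid$nx, x$grid$ny, x$grid$h, x$frequency_hz,
              sqrt(mean(Mod(x$values)^2))))
  invisible(x)
}

#' Single attenuated complex plane wave
#'
#' One local single-wave form `a * exp(omega * (alpha + i beta) . (x - p))`:
#' `beta` (s/m) is the propagation slowness vector — `omega * beta` is the
#' spatial wave vector in rad/m — and `alpha` (s/m) governs the exponential
#' amplitude modulation `exp(omega * alpha . (x - p))`.
#'
#' @param amplitude Complex amplitude `a`.
#' @param beta Slowness 2-vector in s/m; must be nonzero for a propagating
#'   component.
#' @param alpha Attenuation 2-vector in s/m.
#' @param anchor Reference point `p` in meters where the component has
#'   amplitude `a`.
#' @return An object of class `wave_component`.
#' @export
wave_component <- function(amplitude, beta, alpha = c(0, 0), anchor = c(0, 0)) {
  amplitude <- amplitude + 0i
  stopifnot(length(amplitude) == 1L, length(beta) == 2L,
            length(alpha) == 2L, length(anchor) == 2L)
  if (!all(is.finite(c(Re(amplitude), Im(amplitude), beta, alpha, anchor))))
    stop("wave component parameters must be finite")
  if (all(beta == 0)) stop("`beta` must be nonzero for a propagating component")
  structure(list(amplitude = amplitude, beta = as.numeric(beta),
                 alpha = as.numeric(alpha), anchor = as.numeric(anchor)),
            class = "wave_component")
}

## evaluate one component on the tensor grid xs x ys (meters)
eval_component <- function(component, omega, xs, ys) {
  cx <- omega * (component$alpha[1] + 1i * component$beta[1])
  cy <- omega * (component$alpha[2] + 1i * component$beta[2])
  ex <- exp(cx * (xs - component$anchor[1]))
  ey <- exp(cy * (ys - component$anchor[2]))
  component$amplitude * outer(ex, ey)
}

#' Synthesize a multiple-wave field
#'
#' Evaluates the local multiple-wave form
#' `u(x) = sum_n a_n exp(omega (alpha_n + i beta_n) . (x - p_n))`
#' at every pixel center of `grid`.
#'
#' @param components List of [wave_component()] objects (at least one).
#' @param grid An [mre_grid()].
#' @param omega Angular frequency in rad/s.
#' @return A [wave_field()].
#' @export
make_wave_field <- function(components, grid, omega) {
  if (inherits(components, "wave_component")) components <- list(components)
  stopifnot(inherits(grid, "mre_grid"))
  if (length(components) == 0L) stop("at least one wave component is required")
  if (!is.finite(omega) || omega <= 0) stop("`omega` must be positive")
  xs <- grid_x(grid); ys <- grid_y(grid)
  values <- matrix(0i, grid$nx, grid$ny)
  for (cmp in components) {
    if (!inherits(cmp, "wave_component")) stop("components must be `wave_component` objects")
    values <- values + eval_component(cmp, omega, xs, ys)
  }
  wave_field(values, grid, frequency_hz = omega / (2 * pi))
}

#' Assemble a complex field from quadrature snapshots
#'
#' Combines the in-phase image `phi` and the 90-degrees-advanced image
#' `psi` into the complex field `u = phi - i psi`.
#'
#' @param phi,psi Real `nx x ny` matrices on the same grid.
#' @param grid An [mre_grid()].
#' @param frequency_hz Vibration frequency in Hz.
#' @return A [wave_field()].
#' @export
field_from_quadrature <- function(phi, psi, grid, frequency_hz) {
  stopifnot(is.matrix(phi), is.matrix(psi))
  if (!all(dim(phi) == dim(psi))) stop("`phi` and `psi` must have the same shape")
  wave_field(phi - 1i * psi, grid, frequency_hz)
}

#' Stack of real phase-offset snapshots
#'
#' Represents N real snapshots of the wave taken at uniform temporal phase
#' offsets `2*pi*k/N`, `k = 0, ..., N-1`, as acquired by a phase-cycled MRE
#' protocol (e.g. eight snapshots over a full cycle).
#'
#' @param snapshots List of real `nx x ny` matrices (N >= 2).
#' @param grid An [mre_grid()].
#' @param frequency_hz Vibration frequency in Hz.
#' @return An object of class `snapshot_stack` with the implied
#'   `phase_offsets`.
#' @export
snapshot_stack <- function(snapshots, grid, frequency_hz) {
  stopifnot(is.list(snapshots), inherits(grid, "mre_grid"))
  n <- length(snapshots)
  if (n < 2L) stop("at least 2 snapshots are required")
  for (s in snapshots) {
    stopifnot(is.matrix(s), is.numeric(s))
    if (nrow(s) != grid$nx || ncol(s) != grid$ny)
      stop("every snapshot must match the grid dimensions")
  }
  structure(list(snapshots = snapshots, grid = grid,
                 phase_offsets = 2 * pi * (seq_len(n) - 1) / n,
                 frequency_hz = as.numeric(frequency_hz)),
            class = "snapshot_stack")
}

#' Combine phase-offset snapshots into one complex field
#'
#' Extracts the first temporal harmonic of the snapshot stack,
#' `u(x) = (2/N) * sum_k s_k(x) * exp(-i * sign * 2*pi*k/N)`.
#' With snapshots rendered as `s_k = Re(u * exp(+i * 2*pi*k/N))` (the
#' default time convention, `harmonic_sign = 1`) this inverts the
#' rendering exactly for any band-limited field; a DC offset in the
#' snapshots has no first harmonic and drops out.
#'
#' @param stack A [snapshot_stack()].
#' @param harmonic_sign `+1` or `-1`, selecting the temporal phase
#'   convention of the acquisition.
#' @return A [wave_field()].
#' @export
combine_snapshots <- function(stack, harmonic_sign = 1) {
  stopifnot(inherits(stack, "snapshot_stack"))
  if (!harmonic_sign %in% c(-1, 1)) stop("`harmonic_sign` must be +1 or -1")
  n <- length(stack$snapshots)
  u <- matrix(0i, stack$grid$nx, stack$grid$ny)
  for (k in seq_len(n)) {
    u <- u + stack$snapshots[[k]] *
      exp(-1i * harmonic_sign * stack$phase_offsets[k])
  }
  wave_field(2 / n * u, stack$grid, stack$frequency_hz)
}

#' Render real snapshots from a complex field
#'
#' Inverse of [combine_snapshots()]: produces the N real snapshots
#' `s_k(x) = Re(u(x) * exp(i * sign * 2*pi*k/N))`.
#'
#' @param field A [wave_field()].
#' @param n Number of snapshots (>= 2).
#' @inheritParams combine_snapshots
#' @return A [snapshot_stack()].
#' @export
render_snapshots <- function(field, n = 8, harmonic_sign = 1) {
  stopifnot(inherits(field, "wave_field"), n >= 2)
  offs <- 2 * pi * (seq_len(n) - 1) / n
  snaps <- lapply(offs, function(t) Re(field$values * exp(1i * harmonic_sign * t)))
  snapshot_stack(snaps, field$grid, field$frequency_hz)
}

#' Add complex Gaussian white noise at a prescribed signal-to-noise ratio
#'
#' Adds independent zero-mean Gaussian noise to the real and imaginary
#' parts.  The signal-to-noise ratio is defined as
#' `snr = RMS(|u_clean|) / RMS(|noise|)`; the realized noise is scaled so
#' this ratio holds exactly.  With a seed the result is reproducible; the
#' caller's RNG state is left untouched.
#'
#' @param field A [wave_field()].
#' @param snr Positive signal-to-noise ratio (`snr < 1` means the noise
#'   magnitude exceeds the signal).
#' @param seed Optional integer seed.
#' @return A [wave_field()] with the noisy values.
#' @export
add_gaussian_noise <- function(field, snr, seed = NULL) {
  stopifnot(inherits(field, "wave_field"))
  if (!is.finite(snr) || snr <= 0) stop("`snr` must be positive")
  n <- length(field$values)
  raw <- with_preserved_seed(seed, {
    complex(real = stats::rnorm(n, sd = sqrt(0.5)),
            imaginary = stats::rnorm(n, sd = sqrt(0.5)))
  })
  target_rms <- sqrt(mean(Mod(field$values)^2)) / snr
  raw <- raw * (target_rms / sqrt(mean(Mod(raw)^2)))
  wave_field(field$values + matrix(raw, field$grid$nx, field$grid$ny),
             field$grid, field$frequency_hz)
}

## run `expr` under `seed` (if non-NULL) without clobbering the caller's RNG
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
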