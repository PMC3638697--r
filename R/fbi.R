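## even FFT length >= n with small prime factors
even_nextn <- function(n) {
  m <- stats::nextn(n, c(2, 3))
  while (m %% 2L != 0L) m <- stats::nextn(m + 1L, c(2, 3))
  m
}

## fftshift for vectors of FFT frequencies / matrices (even lengths)
fftshift_mat <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((nr / 2 + 1):nr, 1:(nr / 2)), c((nc / 2 + 1):nc, 1:(nc / 2))]
}

#' Gaussian-windowed Fourier transform at a probe point
#'
#' Computes the discrete windowed Fourier transform of the field around a
#' probe point `p`,
#' \deqn{W(\xi) = h^2 \sum_x e^{-i (x-p)\cdot\xi}\, u(x)\,
#'       e^{-|x-p|^2 / 2\sigma^2},}
#' the Riemann-sum discretization of the continuous transform with a
#' Gaussian window of size `sigma`.  The sum runs over a square patch of
#' half-width `patch_halfwidth * sigma` around `p`, clipped at the field
#' boundary; the spectrum is evaluated on a square FFT grid of `xi`
#' values covering `[-pi/h, pi/h)` per axis, refined `pad_factor` times
#' beyond the natural resolution of the patch by zero padding.
#'
#' The kernel is *centered* (`e^{-i(x-p).xi}` rather than `e^{-ix.xi}`),
#' which removes the steep `p . xi` phase ramp; [set_kernel_centering()]
#' converts exactly between the two conventions.  With the `h^2`
#' normalization the continuum closed form [fbi_closed_form()] is the
#' direct oracle for this transform, no rescaling needed.
#'
#' @param field A [wave_field()].
#' @param p Probe point (2-vector, meters); must lie inside the grid.
#' @param sigma Gaussian window size in meters; at least `2h` so the
#'   window is resolvable on the grid.
#' @param pad_factor Integer zero-padding factor for the spectral grid
#'   (default 4).
#' @param patch_halfwidth Patch half-width in units of `sigma`
#'   (default 6; the neglected Gaussian tail is below `1e-8`).
#' @return An object of class `fbi_spectrum`: complex matrix `values`
#'   indexed by (`xi_x`, `xi_y`), the axes in rad/m, the spectral cell
#'   `dxi`, `window_mass` (`h^2` times the summed window, about
#'   `2*pi*sigma^2` away from boundaries), and a `clipped` flag set when
#'   `p` lies within `2*sigma` of the field edge.
#' @export
fbi_transform <- function(field, p, sigma, pad_factor = 4,
                          patch_halfwidth = 6) {
  stopifnot(inherits(field, "wave_field"), length(p) == 2L)
  g <- field$grid
  xs <- grid_x(g); ys <- grid_y(g)
  if (p[1] < xs[1] || p[1] > xs[g$nx] || p[2] < ys[1] || p[2] > ys[g$ny])
    stop("probe point `p` lies outside the field grid")
  if (sigma < 2 * g$h)
    stop("`sigma` must be at least 2 pixels (2h) for the window to be resolvable")
  hw <- patch_halfwidth * sigma
  ii <- which(xs >= p[1] - hw & xs <= p[1] + hw)
  jj <- which(ys >= p[2] - hw & ys <= p[2] + hw)
  ## patch length had the field been unbounded; fixes one xi grid per (field, sigma)
  lfull <- min(max(g$nx, g$ny), 2L * floor(hw / g$h) + 1L)
  m <- even_nextn(pad_factor * lfull)
  wx <- exp(-(xs[ii] - p[1])^2 / (2 * sigma^2))
  wy <- exp(-(ys[jj] - p[2])^2 / (2 * sigma^2))
  gmat <- matrix(0i, m, m)
  gmat[seq_along(ii), seq_along(jj)] <-
    field$values[ii, jj, drop = FALSE] * outer(wx, wy)
  v <- fftshift_mat(stats::fft(gmat))
  dxi <- 2 * pi / (m * g$h)
  xi <- dxi * seq(-m / 2, m / 2 - 1)
  ## centered-kernel phase ramp: patch corner relative to the probe point
  rx <- exp(-1i * (xs[ii[1]] - p[1]) * xi)
  ry <- exp(-1i * (ys[jj[1]] - p[2]) * xi)
  w <- g$h^2 * outer(rx, ry) * v
  dist_edge <- min(p[1] - xs[1], xs[g$nx] - p[1], p[2] - ys[1], ys[g$ny] - p[2])
  structure(list(values = w, xi_x = xi, xi_y = xi, dxi = dxi,
                 p = as.numeric(p), sigma = sigma, omega = field$omega,
                 h = g$h, kernel_centered = TRUE,
                 clipped = dist_edge < 2 * sigma,
                 window_mass = g$h^2 * sum(wx) * sum(wy)),
            class = "fbi_spectrum")
}

#' @export
print.fbi_spectrum <- function(x, ...) {
  cat(sprintf(paste0("<fbi_spectrum> %d x %d xi nodes, dxi = %.3g rad/m, ",
                     "sigma = %g m, p = (%g, %g) m, %s kernel%s\n"),
              nrow(x$values), ncol(x$values), x$dxi, x$sigma, x$p[1], x$p[2],
              if (x$kernel_centered) "centered" else "uncentered",
              if (x$clipped) ", boundary-clipped" else ""))
  invisible(x)
}

#' Switch an FBI spectrum between kernel conventions
#'
#' The centered (`e^{-i(x-p).xi}`) and uncentered (`e^{-ix.xi}`) kernels
#' differ exactly by the unimodular factor `e^{-i p.xi}`; the modulus is
#' unchanged.
#'
#' @param spectrum An `fbi_spectrum`.
#' @param centered Logical; desired convention.
#' @return The converted `fbi_spectrum`.
#' @export
set_kernel_centering <- function(spectrum, centered = TRUE) {
  stopifnot(inherits(spectrum, "fbi_spectrum"))
  if (spectrum$kernel_centered == centered) return(spectrum)
  s <- if (centered) +1 else -1    # multiply by e^{+i p.xi} to center
  fx <- exp(1i * s * spectrum$p[1] * spectrum$xi_x)
  fy <- exp(1i * s * spectrum$p[2] * spectrum$xi_y)
  spectrum$values <- outer(fx, fy) * spectrum$values
  spectrum$kernel_centered <- centered
  spectrum
}

#' Closed-form FBI transform of a single attenuated plane wave
#'
#' For `u(x) = a exp(omega (alpha + i beta) . (x - p))` the continuous
#' Gaussian-windowed transform is
#' \deqn{W(\xi) = 2\pi a \sigma^2
#'   \exp\!\big[i\,\omega^2\sigma^2\,\alpha\cdot\beta +
#'              \tfrac{1}{2}\omega^2\sigma^2|\alpha|^2\big]
#'   \exp\!\big[-i\,(p + \omega\sigma^2\alpha)\cdot\xi -
#'              \tfrac{1}{2}\sigma^2|\xi - \omega\beta|^2\big],}
#' a Gaussian peak of modulus centered exactly at `omega * beta`, with a
#' phase linear in `xi` whose gradient encodes `alpha`.  Components
#' anchored away from the probe point are handled by absorbing the
#' anchor offset into the amplitude.  This is the analytic oracle for
#' [fbi_transform()].
#'
#' @param component A [wave_component()].
#' @param p Probe point (meters).
#' @param sigma Window size (meters).
#' @param omega Angular frequency (rad/s).
#' @param xi Either a 2-vector or an `n x 2` matrix of spatial
#'   frequencies in rad/m.
#' @param centered Logical; when `TRUE` (default) the value is multiplied
#'   by `e^{+i p.xi}`, matching the centered kernel of [fbi_transform()],
#'   whose phase is then `-omega sigma^2 alpha . xi + const`.
#' @return Complex value(s) of the transform at `xi`.
#' @export
fbi_closed_form <- function(component, p, sigma, omega, xi, centered = TRUE) {
  stopifnot(inherits(component, "wave_component"), length(p) == 2L)
  if (is.null(dim(xi))) xi <- matrix(xi, ncol = 2L)
  al <- component$alpha; be <- component$beta
  a_eff <- component$amplitude *
    exp(omega * sum((al + 1i * be) * (p - component$anchor)))
  amp <- 2 * pi * a_eff * sigma^2 *
    exp(1i * omega^2 * sigma^2 * sum(al * be) +
        omega^2 * sigma^2 * sum(al^2) / 2)
  shift <- if (centered) omega * sigma^2 * al else p + omega * sigma^2 * al
  d1 <- xi[, 1] - omega * be[1]; d2 <- xi[, 2] - omega * be[2]
  amp * exp(-1i * (xi[, 1] * shift[1] + xi[, 2] * shift[2]) -
            sigma^2 * (d1^2 + d2^2) / 2)
}

#' Evaluate a closed-form spectrum on a xi grid
#'
#' Convenience wrapper building an `fbi_spectrum` object from
#' [fbi_closed_form()] on a tensor grid of frequencies, mainly for
#' testing the phase-gradient fit against exact data.
#'
#' @inheritParams fbi_closed_form
#' @param xi_x,xi_y Frequency axes in rad/m (uniformly spaced).
#' @return An `fbi_spectrum`.
#' @export
closed_form_spectrum <- function(component, p, sigma, omega, xi_x, xi_y,
                                 centered = TRUE) {
  grid <- as.matrix(expand.grid(xi_x, xi_y))
  vals <- matrix(fbi_closed_form(component, p, sigma, omega, grid, centered),
                 length(xi_x), length(xi_y))
  structure(list(values = vals, xi_x = xi_x, xi_y = xi_y,
                 dxi = if (length(xi_x) > 1) xi_x[2] - xi_x[1] else NA_real_,
                 p = as.numeric(p), sigma = sigma, omega = omega,
                 h = NA_real_, kernel_centered = centered, clipped = FALSE,
                 window_mass = 2 * pi * sigma^2),
            class = "fbi_spectrum")
}

## exact centered-kernel DTFT of the windowed patch at arbitrary xi
## (one value per row of the n x 2 matrix `xi`); used by the denoisers
fbi_eval <- function(field, p, sigma, xi, patch_halfwidth = 6) {
  g <- field$grid
  xs <- grid_x(g); ys <- grid_y(g)
  hw <- patch_halfwidth * sigma
  ii <- which(xs >= p[1] - hw & xs <= p[1] + hw)
  jj <- which(ys >= p[2] - hw & ys <= p[2] + hw)
  wx <- exp(-(xs[ii] - p[1])^2 / (2 * sigma^2))
  wy <- exp(-(ys[jj] - p[2])^2 / (2 * sigma^2))
  gm <- field$values[ii, jj, drop = FALSE] * outer(wx, wy)
  if (is.null(dim(xi))) xi <- matrix(xi, ncol = 2L)
  vapply(seq_len(nrow(xi)), function(k) {
    ex <- exp(-1i * (xs[ii] - p[1]) * xi[k, 1])
    ey <- exp(-1i * (ys[jj] - p[2]) * xi[k, 2])
    g$h^2 * sum(gm * outer(ex, ey))
  }, complex(1))
}
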