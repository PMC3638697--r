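#' Wrapped phase difference of two complex values
#'
#' Returns `arg(w1 * conj(w0))`, the phase difference `arg(w1) - arg(w0)`
#' wrapped to `(-pi, pi]`.  Unlike differencing two arctangents this is
#' continuous across the branch cuts of the arctangent, which is what
#' makes the spectral phase-gradient fit stable.
#'
#' @param w1,w0 Complex scalars (or equal-length vectors); `w0` must be
#'   nonzero.
#' @return Phase difference(s) in radians.
#' @export
phase_difference <- function(w1, w0) {
  if (any(w0 == 0)) stop("reference value `w0` must be nonzero")
  Arg(w1 * Conj(w0))
}

#' Configuration of the spectral phase-gradient fit
#'
#' @param xi0 Reference frequency (2-vector, rad/m) at which the gradient
#'   is evaluated — in the attenuation method, the spectral peak
#'   `omega * beta_hat`.  The nearest spectral node is used as the
#'   reference for phase differences.
#' @param s Gaussian weight width in rad/m for
#'   `w(m, n) = exp(-(m^2 + n^2) / 2 s^2)`; defaults to `1/(2*sigma)`,
#'   half the spectral lobe width of the analysis window.
#' @param radius Stencil radius in spectral cells; defaults to
#'   `max(2, ceiling(3 s / dxi))`.
#' @return An object of class `phase_fit_config`.
#' @export
phase_fit_config <- function(xi0, s = NULL, radius = NULL) {
  stopifnot(length(xi0) == 2L, all(is.finite(xi0)))
  if (!is.null(s) && s <= 0) stop("`s` must be positive")
  if (!is.null(radius) && radius < 1) stop("`radius` must be at least 1")
  structure(list(xi0 = as.numeric(xi0), s = s, radius = radius),
            class = "phase_fit_config")
}

#' Spectral phase gradient by weighted least squares
#'
#' Fits the model `theta(xi) = theta0 + g . (xi - xi_node)` to the
#' wrapped phase differences of the spectrum relative to the node nearest
#' `xi0`, over a square stencil of nodes, with Gaussian weights
#' `exp(-|xi - xi_node|^2 / 2 s^2)`, and returns the slope vector `g`
#' (units: meters, i.e. radians per rad/m).  For the centered-kernel
#' spectrum of a single attenuated wave the phase is exactly linear,
#' `theta = -omega sigma^2 alpha . xi + theta0`, so the fit recovers the
#' attenuation vector without error; the weighted RMS residual is
#' reported as a diagnostic.
#'
#' @param spectrum An `fbi_spectrum`.
#' @param config A [phase_fit_config()].
#' @return List with `gradient` (2-vector), `theta0`, `residual`
#'   (weighted RMS, radians) and `n_nodes`.
#' @export
phase_gradient <- function(spectrum, config) {
  stopifnot(inherits(spectrum, "fbi_spectrum"),
            inherits(config, "phase_fit_config"))
  dxi <- spectrum$dxi
  s <- if (is.null(config$s)) 1 / (2 * spectrum$sigma) else config$s
  radius <- if (is.null(config$radius)) max(2L, ceiling(3 * s / dxi)) else config$radius
  k0 <- which.min(abs(spectrum$xi_x - config$xi0[1]))
  l0 <- which.min(abs(spectrum$xi_y - config$xi0[2]))
  if (k0 - radius < 1L || k0 + radius > length(spectrum$xi_x) ||
      l0 - radius < 1L || l0 + radius > length(spectrum$xi_y))
    stop("phase-fit stencil is not fully contained in the spectral grid")
  w0 <- spectrum$values[k0, l0]
  if (w0 == 0) stop("reference spectral value is zero")
  kk <- (k0 - radius):(k0 + radius)
  ll <- (l0 - radius):(l0 + radius)
  sub <- spectrum$values[kk, ll]
  m <- spectrum$xi_x[kk] - spectrum$xi_x[k0]
  n <- spectrum$xi_y[ll] - spectrum$xi_y[l0]
  mm <- matrix(m, length(kk), length(ll))
  nn <- matrix(n, length(kk), length(ll), byrow = TRUE)
  theta <- Arg(sub * Conj(w0))
  wts <- exp(-(mm^2 + nn^2) / (2 * s^2))
  x <- cbind(1, as.vector(mm), as.vector(nn))
  fit <- stats::lm.wfit(x, as.vector(theta), as.vector(wts))
  if (fit$qr$rank < 3L) stop("degenerate phase-fit stencil (singular normal equations)")
  co <- fit$coefficients
  res <- sqrt(sum(as.vector(wts) * fit$residuals^2) / sum(wts))
  list(gradient = unname(co[2:3]), theta0 = unname(co[1]),
       residual = res, n_nodes = length(theta))
}

#' Local attenuation vector at one probe point
#'
#' Estimates the attenuation vector of the locally strongest plane-wave
#' component from the gradient of the FBI-spectrum phase at the spectral
#' peak: with the centered kernel,
#' `alpha = -grad_xi theta / (omega sigma^2)`, evaluated at
#' `xi0 = omega * beta_hat`.
#'
#' @inheritParams fbi_transform
#' @param beta_hat Local wave vector at `p` (s/m), from
#'   [local_wave_vector()].
#' @param s,radius Phase-fit parameters, see [phase_fit_config()].
#' @return Numeric 2-vector `alpha` in s/m with attribute `residual`
#'   (the weighted RMS fit residual).  A warning is issued when
#'   `omega * |alpha| * sigma > 1`, where the single-Gaussian-peak model
#'   of the spectrum starts to degrade.
#' @export
local_attenuation_vector <- function(field, p, sigma, beta_hat,
                                     s = NULL, radius = NULL,
                                     pad_factor = 4, patch_halfwidth = 6) {
  stopifnot(length(beta_hat) == 2L)
  sp <- fbi_transform(field, p, sigma, pad_factor, patch_halfwidth)
  fit <- phase_gradient(sp, phase_fit_config(field$omega * as.numeric(beta_hat),
                                             s = s, radius = radius))
  alpha <- -fit$gradient / (field$omega * sigma^2)
  if (field$omega * sqrt(sum(alpha^2)) * sigma > 1)
    warning("omega * |alpha| * sigma > 1: Gaussian-peak model degrading, estimate unreliable")
  attr(alpha, "residual") <- fit$residual
  alpha
}

#' Map of local attenuation (and wave) vectors over a field
#'
#' Same sampling scheme as [wave_vector_map()], with the attenuation
#' vector estimated at each sample point from the spectral phase gradient
#' at that point's own peak.  Points where the phase-fit stencil falls
#' off the spectral grid carry `NA` attenuation.
#'
#' @inheritParams wave_vector_map
#' @inheritParams local_attenuation_vector
#' @return A `vector_field_map` with additional columns `alpha_x`,
#'   `alpha_y` and `fit_residual`.
#' @export
attenuation_map <- function(field, spacing = 4, sigma, margin = 2 * sigma,
                            s = NULL, radius = NULL, pad_factor = 4,
                            min_xi_norm = NULL, patch_halfwidth = 6) {
  map_sample_points(field, spacing, sigma, margin, with_alpha = TRUE,
                    pad_factor = pad_factor, min_xi_norm = min_xi_norm,
                    patch_halfwidth = patch_halfwidth, s = s, radius = radius)
}
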