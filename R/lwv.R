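## Shared 2-D peak finder with separable log-quadratic sub-cell refinement.
## Returns list(xi, magnitude, node, offset) or errors when all nodes are
## masked by `min_xi_norm`.
find_spectral_peak <- function(mag, xi_x, xi_y, min_xi_norm) {
  nrm <- sqrt(outer(xi_x^2, xi_y^2, "+"))
  ok <- nrm >= min_xi_norm
  if (!any(ok)) stop("all spectral nodes are masked by `min_xi_norm`")
  mm <- mag
  mm[!ok] <- -Inf
  mx <- max(mm)
  cand <- which(mm >= mx * (1 - 1e-12) & is.finite(mm), arr.ind = TRUE)
  if (nrow(cand) > 1L) {
    ## ties: smallest |xi| first, then lexicographic index order
    nn <- nrm[cand]
    cand <- cand[order(nn, cand[, 1], cand[, 2]), , drop = FALSE]
  }
  k <- unname(cand[1, 1]); l <- unname(cand[1, 2])
  refine <- function(vals) {
    ## log-quadratic through three points; exact for a Gaussian profile
    if (any(!is.finite(vals)) || any(vals <= 0)) return(c(0, log(max(vals[2], .Machine$double.xmin))))
    ## neighbors at round-off level: the peak is a resolved delta, keep the node
    if (min(vals[c(1, 3)]) < 1e-8 * vals[2]) return(c(0, log(vals[2])))
    lv <- log(vals)
    den <- lv[1] - 2 * lv[2] + lv[3]
    if (den >= 0) return(c(0, lv[2]))
    d <- 0.5 * (lv[1] - lv[3]) / den
    d <- max(min(d, 0.5), -0.5)
    c(d, lv[2] - 0.25 * (lv[1] - lv[3]) * d)
  }
  off <- c(0, 0); lpk <- log(max(mag[k, l], .Machine$double.xmin))
  corr <- 0
  if (k > 1L && k < length(xi_x)) {
    r <- refine(c(mag[k - 1, l], mag[k, l], mag[k + 1, l]))
    off[1] <- r[1]; corr <- corr + (r[2] - lpk)
  }
  if (l > 1L && l < length(xi_y)) {
    r <- refine(c(mag[k, l - 1], mag[k, l], mag[k, l + 1]))
    off[2] <- r[1]; corr <- corr + (r[2] - lpk)
  }
  dx <- if (length(xi_x) > 1) xi_x[2] - xi_x[1] else 0
  dy <- if (length(xi_y) > 1) xi_y[2] - xi_y[1] else 0
  list(xi = c(xi_x[k] + off[1] * dx, xi_y[l] + off[2] * dy),
       magnitude = exp(lpk + corr),
       node = c(k, l), offset = off)
}

#' Dominant peak of an FBI spectrum
#'
#' Locates the maximum of `|W|` over spectral nodes with
#' `|xi| >= min_xi_norm` and refines it to sub-cell precision with a
#' separable log-quadratic fit through the peak node and its axis
#' neighbors (exact for the Gaussian peak shape the single-wave closed
#' form predicts).  Ties are broken toward the smallest `|xi|` — the
#' physically longer wavelength — then by index order.
#'
#' @param spectrum An `fbi_spectrum` from [fbi_transform()].
#' @param min_xi_norm Radius of the excluded low-frequency disc in rad/m;
#'   defaults to one spectral cell, which stops a DC offset from winning
#'   the argmax.
#' @return List with `xi` (refined peak location, rad/m), `magnitude`
#'   (refined `|W|`), `node` (matrix indices) and `offset` (sub-cell
#'   shift in cells).
#' @export
spectral_peak <- function(spectrum, min_xi_norm = NULL) {
  stopifnot(inherits(spectrum, "fbi_spectrum"))
  if (is.null(min_xi_norm)) min_xi_norm <- spectrum$dxi
  find_spectral_peak(Mod(spectrum$values), spectrum$xi_x, spectrum$xi_y,
                     min_xi_norm)
}

#' Local wave vector at one probe point
#'
#' The slowness vector of the locally strongest plane-wave component:
#' `beta = argmax_xi |W(u; p, sigma)(xi)| / omega`.
#'
#' @inheritParams fbi_transform
#' @inheritParams spectral_peak
#' @return Numeric 2-vector `beta` in s/m, with attributes `peak_mag`
#'   (spectral peak modulus) and `xi` (peak location in rad/m).
#' @export
local_wave_vector <- function(field, p, sigma, pad_factor = 4,
                              min_xi_norm = NULL, patch_halfwidth = 6) {
  sp <- fbi_transform(field, p, sigma, pad_factor, patch_halfwidth)
  pk <- spectral_peak(sp, min_xi_norm)
  beta <- pk$xi / field$omega
  attr(beta, "peak_mag") <- pk$magnitude
  attr(beta, "xi") <- pk$xi
  beta
}

## shared worker for wave_vector_map / attenuation_map
map_sample_points <- function(field, spacing, sigma, margin, with_alpha,
                              pad_factor = 4, min_xi_norm = NULL,
                              patch_halfwidth = 6, s = NULL, radius = NULL) {
  stopifnot(inherits(field, "wave_field"), spacing >= 1)
  g <- field$grid
  xs <- grid_x(g); ys <- grid_y(g)
  ix <- seq(1L, g$nx, by = as.integer(spacing))
  iy <- seq(1L, g$ny, by = as.integer(spacing))
  ix <- ix[xs[ix] >= xs[1] + margin & xs[ix] <= xs[g$nx] - margin]
  iy <- iy[ys[iy] >= ys[1] + margin & ys[iy] <= ys[g$ny] - margin]
  if (length(ix) == 0L || length(iy) == 0L)
    stop("no sample points: margin leaves no interior pixels")
  pts <- expand.grid(i = ix, j = iy)
  n <- nrow(pts)
  res <- data.frame(x_m = xs[pts$i], y_m = ys[pts$j],
                    beta_x = NA_real_, beta_y = NA_real_,
                    xi_x = NA_real_, xi_y = NA_real_,
                    peak_mag = NA_real_, clipped = FALSE,
                    low_contrast = FALSE)
  if (with_alpha) {
    res$alpha_x <- NA_real_; res$alpha_y <- NA_real_
    res$fit_residual <- NA_real_
  }
  for (r in seq_len(n)) {
    p <- c(res$x_m[r], res$y_m[r])
    sp <- fbi_transform(field, p, sigma, pad_factor, patch_halfwidth)
    pk <- spectral_peak(sp, min_xi_norm)
    res$xi_x[r] <- pk$xi[1]; res$xi_y[r] <- pk$xi[2]
    res$beta_x[r] <- pk$xi[1] / field$omega
    res$beta_y[r] <- pk$xi[2] / field$omega
    res$peak_mag[r] <- pk$magnitude
    res$clipped[r] <- sp$clipped
    res$low_contrast[r] <- pk$magnitude < 3 * stats::median(Mod(sp$values))
    if (with_alpha) {
      fit <- try(phase_gradient(sp, phase_fit_config(pk$xi, s = s,
                                                     radius = radius)),
                 silent = TRUE)
      if (!inherits(fit, "try-error")) {
        al <- -fit$gradient / (field$omega * sigma^2)
        res$alpha_x[r] <- al[1]; res$alpha_y[r] <- al[2]
        res$fit_residual[r] <- fit$residual
      }
    }
  }
  attr(res, "omega") <- field$omega
  attr(res, "sigma") <- sigma
  attr(res, "spacing") <- spacing
  attr(res, "margin") <- margin
  class(res) <- c("vector_field_map", "data.frame")
  res
}

#' Map of local wave vectors over a field
#'
#' Runs [local_wave_vector()] on a regular lattice of sample points at
#' least `margin` from the field boundary.  With `margin = 0` points near
#' the edge are kept but carry the `clipped` quality flag (probe closer
#' than `2*sigma` to the edge); `low_contrast` flags peaks that barely
#' rise above the spectral floor.
#'
#' @inheritParams local_wave_vector
#' @param spacing Sample spacing in pixels (default 4).
#' @param margin Minimum distance of sample points from the field edge in
#'   meters (default `2*sigma`).
#' @return A data frame of class `vector_field_map` with columns `x_m`,
#'   `y_m`, `beta_x`, `beta_y`, `xi_x`, `xi_y`, `peak_mag`, `clipped`,
#'   `low_contrast`.
#' @export
wave_vector_map <- function(field, spacing = 4, sigma, margin = 2 * sigma,
                            pad_factor = 4, min_xi_norm = NULL,
                            patch_halfwidth = 6) {
  map_sample_points(field, spacing, sigma, margin, with_alpha = FALSE,
                    pad_factor = pad_factor, min_xi_norm = min_xi_norm,
                    patch_halfwidth = patch_halfwidth)
}

#' Window size suggestion from the global spectrum
#'
#' Practical experience with windowed wave-vector estimation puts the
#' Gaussian window between half and one dominant wavelength.  The
#' dominant wavelength is read off the global spectral peak:
#' `sigma = factor * 2*pi / |xi_inf|`.
#'
#' @param field A [wave_field()].
#' @param factor Fraction of the dominant wavelength (default 0.75;
#'   warned about outside `[0.5, 1]`).
#' @param min_peak_contrast Minimum ratio of the global peak modulus to
#'   the median spectral modulus; below it the spectrum is considered
#'   degenerate (e.g. pure noise) and an error is raised.
#' @return Window size `sigma` in meters.
#' @export
suggest_sigma <- function(field, factor = 0.75, min_peak_contrast = 5) {
  if (factor < 0.5 || factor > 1)
    warning("`factor` outside [0.5, 1]: window size outside the usual half to one wavelength")
  pk <- global_spectrum_peak(field, details = TRUE)
  if (pk$magnitude < min_peak_contrast * pk$median_mag)
    stop("degenerate global spectrum: no dominant wave peak")
  factor * 2 * pi / sqrt(sum(pk$xi^2))
}
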