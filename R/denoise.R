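#' Peak of the global Fourier spectrum
#'
#' Locates the maximum modulus of the full-field discrete Fourier
#' transform over frequencies with `|xi| >= min_xi_norm`, refined to
#' sub-cell precision like [spectral_peak()].  This is the wave vector of
#' the globally strongest plane-wave component, used by the global
#' denoising filter and by [suggest_sigma()].
#'
#' @param field A [wave_field()].
#' @param min_xi_norm Excluded low-frequency radius in rad/m (default:
#'   one spectral cell of the longer axis).
#' @param details When `TRUE` return a list with `xi`, `magnitude` and
#'   the median spectral modulus instead of the bare location.
#' @return Numeric 2-vector `xi_inf` in rad/m (with attribute
#'   `magnitude`), or the detail list.
#' @export
global_spectrum_peak <- function(field, min_xi_norm = NULL, details = FALSE) {
  stopifnot(inherits(field, "wave_field"))
  g <- field$grid
  if (g$nx %% 2L || g$ny %% 2L)
    stop("global spectrum requires even grid dimensions")
  v <- fftshift_mat(stats::fft(field$values))
  mag <- Mod(v)
  if (max(mag) - min(mag) <= 1e-12 * max(mag, .Machine$double.xmin))
    stop("degenerate (flat) global spectrum")
  dxx <- 2 * pi / (g$nx * g$h); dxy <- 2 * pi / (g$ny * g$h)
  xi_x <- dxx * seq(-g$nx / 2, g$nx / 2 - 1)
  xi_y <- dxy * seq(-g$ny / 2, g$ny / 2 - 1)
  if (is.null(min_xi_norm)) min_xi_norm <- max(dxx, dxy)
  pk <- find_spectral_peak(mag, xi_x, xi_y, min_xi_norm)
  if (details) {
    nrm <- sqrt(outer(xi_x^2, xi_y^2, "+"))
    return(list(xi = pk$xi, magnitude = pk$magnitude,
                median_mag = stats::median(mag[nrm >= min_xi_norm])))
  }
  out <- pk$xi
  attr(out, "magnitude") <- pk$magnitude
  out
}

#' Configuration of the strongest-peak spectral filters
#'
#' @param sigma Gaussian analysis window size in meters.
#' @param mode `"local"`: each tile keeps its own strongest spectral
#'   peak; `"global"`: every tile keeps the fixed global peak `xi_inf`.
#' @param gamma Spectral width in rad/m of the Gaussian window replacing
#'   the delta filter; `0` (default) selects the pure single-frequency
#'   (delta) filter.
#' @param tile Tile size in pixels — the "pixel" over which each filtered
#'   plane wave is pasted back (default 4; `1` reproduces per-pixel
#'   filtering at higher cost).
#' @param min_xi_norm Excluded low-frequency radius for the peak search
#'   (rad/m); default one spectral cell.
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(sigma, mode = c("local", "global"), gamma = 0,
                           tile = 4, min_xi_norm = NULL) {
  mode <- match.arg(mode)
  stopifnot(sigma > 0, gamma >= 0, tile >= 1)
  structure(list(sigma = sigma, mode = mode, gamma = gamma,
                 tile = as.integer(tile), min_xi_norm = min_xi_norm),
            class = "denoise_config")
}

## core of both filters: reconstruct each tile from one (or a Gaussian
## packet of) spectral component(s) of its own FBI spectrum
run_denoise <- function(field, config, xi_fixed = NULL) {
  stopifnot(inherits(field, "wave_field"), inherits(config, "denoise_config"))
  g <- field$grid
  if (config$tile > min(g$nx, g$ny)) stop("tile size exceeds the field")
  xs <- grid_x(g); ys <- grid_y(g)
  out <- matrix(0i, g$nx, g$ny)
  bx <- seq(1L, g$nx, by = config$tile)
  by <- seq(1L, g$ny, by = config$tile)
  for (i0 in bx) {
    ii <- i0:min(i0 + config$tile - 1L, g$nx)
    for (j0 in by) {
      jj <- j0:min(j0 + config$tile - 1L, g$ny)
      p <- c(mean(xs[ii]), mean(ys[jj]))
      need_spectrum <- is.null(xi_fixed) || config$gamma > 0
      sp <- if (need_spectrum) fbi_transform(field, p, config$sigma) else NULL
      xi_hat <- if (is.null(xi_fixed)) {
        spectral_peak(sp, config$min_xi_norm)$xi
      } else xi_fixed
      wm <- window_mass_at(field, p, config$sigma)
      if (config$gamma == 0) {
        a <- fbi_eval(field, p, config$sigma, xi_hat) / wm
        ex <- exp(1i * (xs[ii] - p[1]) * xi_hat[1])
        ey <- exp(1i * (ys[jj] - p[2]) * xi_hat[2])
        out[ii, jj] <- a * outer(ex, ey)
      } else {
        d2 <- outer((sp$xi_x - xi_hat[1])^2, (sp$xi_y - xi_hat[2])^2, "+")
        keep <- which(d2 <= (4 * config$gamma)^2, arr.ind = TRUE)
        if (nrow(keep) == 0L)
          keep <- which(d2 == min(d2), arr.ind = TRUE)[1, , drop = FALSE]
        wts <- exp(-d2[keep] / (2 * config$gamma^2))
        wts <- wts / sum(wts)                     # unit-mass spectral window
        tile_vals <- matrix(0i, length(ii), length(jj))
        for (q in seq_len(nrow(keep))) {
          xq <- sp$xi_x[keep[q, 1]]; yq <- sp$xi_y[keep[q, 2]]
          aq <- sp$values[keep[q, 1], keep[q, 2]] / wm
          tile_vals <- tile_vals + wts[q] * aq *
            outer(exp(1i * (xs[ii] - p[1]) * xq), exp(1i * (ys[jj] - p[2]) * yq))
        }
        out[ii, jj] <- tile_vals
      }
    }
  }
  wave_field(out, g, field$frequency_hz)
}

## discrete Gaussian window mass h^2 * sum(w) over the (clipped) patch;
## equals 2*pi*sigma^2 to high accuracy away from boundaries.  Dividing
## the spectral peak value by this mass makes the delta filter the exact
## identity on a single plane wave even where the patch is clipped.
window_mass_at <- function(field, p, sigma, patch_halfwidth = 6) {
  g <- field$grid
  xs <- grid_x(g); ys <- grid_y(g)
  hw <- patch_halfwidth * sigma
  wx <- exp(-(xs[xs >= p[1] - hw & xs <= p[1] + hw] - p[1])^2 / (2 * sigma^2))
  wy <- exp(-(ys[ys >= p[2] - hw & ys <= p[2] + hw] - p[2])^2 / (2 * sigma^2))
  g$h^2 * sum(wx) * sum(wy)
}

#' Strongest-local-peak spectral filter
#'
#' For each tile of pixels, replaces the field by the single plane wave
#' corresponding to the strongest peak of that tile's Gaussian-windowed
#' spectrum: the tile's output is
#' `W(u; p, sigma)(xi(p)) / m(p) * exp(i (x - p) . xi(p))` where `xi(p)`
#' is the refined spectral argmax and `m(p)` the discrete window mass
#' (about `2*pi*sigma^2`).  The filtered field is the superposition of
#' the tiles (characteristic-function paste-back), so discontinuities can
#' appear where neighboring tiles lock onto different waves.  With
#' `gamma > 0` the single component is replaced by a unit-mass Gaussian
#' packet of width `gamma` around the peak, which relaxes the filter
#' continuously back towards the raw spectrum.
#'
#' @param field A [wave_field()].
#' @param config A [denoise_config()].
#' @return The filtered [wave_field()].
#' @export
denoise_local <- function(field, config) {
  run_denoise(field, config, xi_fixed = NULL)
}

#' Globally-strongest-peak spectral filter
#'
#' Identical to [denoise_local()] except that every tile keeps the same
#' fixed frequency `xi_inf`, the peak of the global Fourier spectrum, so
#' the output is close to a single sinusoidal wave.
#'
#' @inheritParams denoise_local
#' @return The filtered [wave_field()].
#' @export
denoise_global <- function(field, config) {
  xi_inf <- global_spectrum_peak(field, min_xi_norm = config$min_xi_norm)
  run_denoise(field, config, xi_fixed = as.numeric(xi_inf))
}

#' Total variation of the real part of a field
#'
#' Sum of absolute first differences along both axes; a simple roughness
#' measure used to quantify the smoothing effect of the filters.
#'
#' @param field A [wave_field()].
#' @return Scalar total variation.
#' @export
total_variation <- function(field) {
  v <- Re(field$values)
  sum(abs(diff(v))) + sum(abs(t(diff(t(v)))))
}
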