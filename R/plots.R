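#' Quiver overlay of estimated vectors on the wave image
#'
#' Draws `Re u` as a raster with the per-point `beta` (or `alpha`)
#' vectors superimposed as arrows, the standard way of inspecting a
#' local wave-vector fit.  Arrow lengths are scaled so the longest one
#' spans about `arrow_frac` of the image.
#'
#' @param field A [wave_field()].
#' @param vmap A `vector_field_map`.
#' @param component `"beta"` or `"alpha"`.
#' @param arrow_frac Fraction of the image width for the longest arrow.
#' @return A ggplot object.
#' @export
plot_vector_overlay <- function(field, vmap, component = c("beta", "alpha"),
                                arrow_frac = 0.08) {
  component <- match.arg(component)
  g <- field$grid
  img <- data.frame(x = rep(grid_x(g), times = g$ny),
                    y = rep(grid_y(g), each = g$nx),
                    re = as.vector(Re(field$values)))
  vx <- vmap[[paste0(component, "_x")]]
  vy <- vmap[[paste0(component, "_y")]]
  keep <- is.finite(vx) & is.finite(vy)
  len <- sqrt(vx^2 + vy^2)
  scale <- arrow_frac * (max(grid_x(g)) - min(grid_x(g))) /
    max(len[keep], .Machine$double.eps)
  arr <- data.frame(x = vmap$x_m[keep], y = vmap$y_m[keep],
                    xend = vmap$x_m[keep] + scale * vx[keep],
                    yend = vmap$y_m[keep] + scale * vy[keep])
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = img, ggplot2::aes(x = .data$x, y = .data$y,
                                                  fill = .data$re)) +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey60",
                                  high = "white", name = "Re u") +
    ggplot2::geom_segment(data = arr,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(3, "pt")),
                          color = "red", linewidth = 0.3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = sprintf("local %s vectors", component))
}

#' Grayscale map of a recovered modulus
#'
#' @param mmap A [moduli_map()].
#' @param quantity `"Gp"` or `"Gpp"`.
#' @return A ggplot object (masked points are omitted).
#' @export
plot_modulus_map <- function(mmap, quantity = c("Gp", "Gpp")) {
  quantity <- match.arg(quantity)
  col <- if (quantity == "Gp") "Gp_Pa" else "Gpp_Pa"
  d <- as.data.frame(mmap)
  d <- d[d$valid & is.finite(d[[col]]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_m, y = .data$y_m,
                                  fill = .data[[col]] / 1000)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = sprintf("%s (kPa)",
                                                if (quantity == "Gp") "G'" else "G''")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Modulus image of a spectrum
#'
#' Displays `|W|` of an FBI spectrum, or the global Fourier modulus of a
#' field, in the spatial-frequency plane.
#'
#' @param x An `fbi_spectrum` or a [wave_field()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(x) {
  if (inherits(x, "wave_field")) {
    g <- x$grid
    v <- fftshift_mat(stats::fft(x$values))
    xi_x <- 2 * pi / (g$nx * g$h) * seq(-g$nx / 2, g$nx / 2 - 1)
    xi_y <- 2 * pi / (g$ny * g$h) * seq(-g$ny / 2, g$ny / 2 - 1)
  } else if (inherits(x, "fbi_spectrum")) {
    v <- x$values; xi_x <- x$xi_x; xi_y <- x$xi_y
  } else stop("`x` must be a wave_field or fbi_spectrum")
  d <- data.frame(xi_x = rep(xi_x, times = length(xi_y)),
                  xi_y = rep(xi_y, each = length(xi_x)),
                  mag = as.vector(Mod(v)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$xi_x, y = .data$xi_y,
                                  fill = .data$mag)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = "|W|") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = expression(xi[1] ~ "(rad/m)"),
                  y = expression(xi[2] ~ "(rad/m)"))
}
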