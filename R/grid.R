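#' Regular 2-D pixel grid with metric coordinates
#'
#' Describes the geometry of a wave image: pixel counts, isotropic pixel
#' spacing in meters and the physical coordinate of pixel `(0, 0)`.
#' Pixel `(i, j)` (0-based) sits at `origin + (i*h, j*h)`; the x axis
#' increases rightward, the y axis upward, and all quantities are SI.
#'
#' @param nx,ny Integer pixel counts (at least 4 each).
#' @param h Pixel spacing in meters (scalar, positive).
#' @param origin Physical coordinate of pixel `(0, 0)` in meters.
#' @return An object of class `mre_grid`.
#' @examples
#' g <- mre_grid(64, 64, h = 1.2e-3)
#' range(grid_x(g))
#' @export
mre_grid <- function(nx, ny, h, origin = c(0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(length(nx) == 1L, length(ny) == 1L, length(h) == 1L,
            length(origin) == 2L)
  if (!is.finite(h) || h <= 0) stop("pixel spacing `h` must be positive")
  if (nx < 4L || ny < 4L) stop("grid must have at least 4 pixels per axis")
  if (!all(is.finite(origin))) stop("`origin` must be finite")
  structure(list(nx = nx, ny = ny, h = as.numeric(h),
                 origin = as.numeric(origin)),
            class = "mre_grid")
}

#' @rdname mre_grid
#' @param grid An `mre_grid`.
#' @export
grid_x <- function(grid) grid$origin[1] + (seq_len(grid$nx) - 1) * grid$h

#' @rdname mre_grid
#' @export
grid_y <- function(grid) grid$origin[2] + (seq_len(grid$ny) - 1) * grid$h

#' @export
print.mre_grid <- function(x, ...) {
  cat(sprintf("<mre_grid> %d x %d pixels, h = %g m, origin = (%g, %g) m\n",
              x$nx, x$ny, x$h, x$origin[1], x$origin[2]))
  invisible(x)
}

same_grid <- function(a, b) {
  a$nx == b$nx && a$ny == b$ny &&
    isTRUE(all.equal(a$h, b$h)) && isTRUE(all.equal(a$origin, b$origin))
}
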