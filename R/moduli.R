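#' Complex shear modulus from local wave and attenuation vectors
#'
#' For a nearly incompressible isotropic viscoelastic medium, a local
#' single-wave form with slowness vector `beta` and attenuation vector
#' `alpha` satisfies the dispersion relation
#' `rho + (G' + i G'') * (alpha + i beta) . (alpha + i beta) = 0`,
#' which inverts to
#' \deqn{(G', G'') = \frac{\rho}{(|\alpha|^2-|\beta|^2)^2 + 4(\alpha\cdot\beta)^2}
#'       \,(|\beta|^2 - |\alpha|^2,\; 2\,\alpha\cdot\beta).}
#' `G''` may come out negative when a noisy `alpha` flips against `beta`;
#' it is reported as computed, not clipped.
#'
#' @param alpha,beta Attenuation and slowness 2-vectors in s/m.
#' @param rho Density in kg/m^3 (defaults to 1000, soft tissue / gel).
#' @return Named numeric vector `c(Gp = , Gpp = )` in Pa.
#' @seealso [vectors_from_moduli()] for the inverse map,
#'   [storage_modulus_approx()] for the lossless shortcut.
#' @export
moduli_from_vectors <- function(alpha, beta, rho = 1000) {
  stopifnot(length(alpha) == 2L, length(beta) == 2L, rho > 0)
  if (all(alpha == 0) && all(beta == 0)) stop("(alpha, beta) must be nonzero")
  a2 <- sum(alpha^2); b2 <- sum(beta^2); ab <- sum(alpha * beta)
  den <- (a2 - b2)^2 + 4 * ab^2
  if (den == 0)
    stop("degenerate vectors: |alpha| = |beta| and alpha . beta = 0 (zero denominator)")
  c(Gp = rho * (b2 - a2) / den, Gpp = rho * 2 * ab / den)
}

#' Lossless-limit storage modulus
#'
#' When attenuation is negligible the dispersion relation reduces to
#' `G' = rho / |beta|^2` (equivalently `G' = rho c^2` with phase speed
#' `c = 1/|beta|`): stiffer tissue, longer wavelength, shorter slowness.
#'
#' @inheritParams moduli_from_vectors
#' @return Storage modulus G' in Pa.
#' @export
storage_modulus_approx <- function(beta, rho = 1000) {
  stopifnot(length(beta) == 2L, rho > 0)
  b2 <- sum(beta^2)
  if (b2 == 0) stop("|beta| must be positive")
  rho / b2
}

#' Slowness and attenuation vectors realizing prescribed moduli
#'
#' Inverse of [moduli_from_vectors()], used by the simulator: finds
#' `(alpha, beta)` satisfying the dispersion relation exactly for given
#' `(G', G'')`, with `beta` along `beta_dir` and `alpha` rotated by
#' `angle_alpha_beta` (counterclockwise) from `beta`.  Writing
#' `A = -G' rho / (G'^2 + G''^2)` and `B = G'' rho / (G'^2 + G''^2)`,
#' the constraints are `|alpha|^2 - |beta|^2 = A` and
#' `2 |alpha||beta| cos(angle) = B`; a real solution requires
#' `sign(cos(angle)) == sign(G'')` (any magnitude of the cosine works),
#' and `G'' = 0` forces `alpha = 0`.
#'
#' @param Gp Storage modulus in Pa (positive).
#' @param Gpp Loss modulus in Pa (non-negative here; the forward map can
#'   still produce negative values from noisy vectors).
#' @param rho Density in kg/m^3.
#' @param beta_dir Unit 2-vector giving the direction of `beta`
#'   (normalized internally).
#' @param angle_alpha_beta Angle from `beta` to `alpha` in radians; ignored
#'   when `Gpp = 0`.
#' @return List with elements `alpha` and `beta` (2-vectors, s/m).
#' @export
vectors_from_moduli <- function(Gp, Gpp, rho = 1000,
                                beta_dir = c(1, 1) / sqrt(2),
                                angle_alpha_beta = NULL) {
  stopifnot(Gp > 0, rho > 0, length(beta_dir) == 2L)
  nb <- sqrt(sum(beta_dir^2))
  if (nb == 0) stop("`beta_dir` must be nonzero")
  beta_dir <- beta_dir / nb
  A <- -Gp * rho / (Gp^2 + Gpp^2)
  B <- Gpp * rho / (Gp^2 + Gpp^2)
  if (Gpp == 0) {
    b <- sqrt(rho / Gp)
    return(list(alpha = c(0, 0), beta = b * beta_dir))
  }
  if (is.null(angle_alpha_beta))
    angle_alpha_beta <- alpha_angle_for_ratio(Gp, Gpp, rho)
  cs <- cos(angle_alpha_beta)
  if (sign(cs) != sign(B) || cs == 0)
    stop(sprintf(paste0("infeasible angle between alpha and beta: G'' = %g Pa ",
                        "requires cos(angle) in (%s]; got cos(angle) = %.3g"),
                 Gpp, if (B > 0) "0, 1" else "-1, 0", cs))
  b2 <- (-A + sqrt(A^2 + B^2 / cs^2)) / 2
  b <- sqrt(b2)
  a <- B / (2 * b * cs)
  rot <- matrix(c(cos(angle_alpha_beta), sin(angle_alpha_beta),
                  -sin(angle_alpha_beta), cos(angle_alpha_beta)), 2, 2)
  list(alpha = a * as.numeric(rot %*% beta_dir), beta = b * beta_dir)
}

#' Angle between alpha and beta yielding a prescribed length ratio
#'
#' Finds the angle such that [vectors_from_moduli()] returns vectors with
#' `|alpha| = ratio * |beta|`.  The default ratio 1/10 is the small
#' attenuation typical of gel phantoms and soft tissue.
#'
#' @inheritParams vectors_from_moduli
#' @param ratio Target `|alpha| / |beta|` in (0, 1).
#' @return Angle in radians (positive, counterclockwise from `beta`).
#' @export
alpha_angle_for_ratio <- function(Gp, Gpp, rho = 1000, ratio = 0.1) {
  stopifnot(Gp > 0, Gpp > 0, rho > 0, ratio > 0, ratio < 1)
  A <- -Gp * rho / (Gp^2 + Gpp^2)
  B <- Gpp * rho / (Gp^2 + Gpp^2)
  b2 <- -A / (1 - ratio^2)          # from |alpha|^2 - |beta|^2 = A with |alpha| = r|beta|
  cs <- B / (2 * ratio * b2)
  if (abs(cs) > 1)
    stop(sprintf("ratio %g infeasible for G' = %g, G'' = %g (needs |cos| = %.3g)",
                 ratio, Gp, Gpp, cs))
  acos(cs)
}

#' Per-point moduli map from a vector-field map
#'
#' Applies the dispersion relation at every sample point of a
#' [wave_vector_map()] / [attenuation_map()] result.  When attenuation
#' vectors are present the full relation is used; otherwise the lossless
#' approximation `G' = rho/|beta|^2` (and `G''` is `NA`).  Points are
#' masked, with a reason code, when the estimated `|beta|` falls below
#' `low_beta_cutoff` times the median `|beta|` (near-zero slowness makes
#' `G'` blow up, typically in wave shadows), when the probe point was
#' boundary-clipped, or when the computed `G'` is not positive.
#'
#' @param vmap A `vector_field_map` as returned by [wave_vector_map()] or
#'   [attenuation_map()].
#' @param rho Density in kg/m^3.
#' @param low_beta_cutoff Fraction of the median `|beta|` below which a
#'   point is masked (default 0.1).
#' @return A data frame of class `moduli_map` with columns `x_m`, `y_m`,
#'   `Gp_Pa`, `Gpp_Pa`, `valid` and `reason`.
#' @export
moduli_map <- function(vmap, rho = 1000, low_beta_cutoff = 0.1) {
  stopifnot(inherits(vmap, "vector_field_map"))
  if (nrow(vmap) == 0L) stop("empty vector-field map")
  has_alpha <- all(c("alpha_x", "alpha_y") %in% names(vmap))
  bnorm <- sqrt(vmap$beta_x^2 + vmap$beta_y^2)
  med <- stats::median(bnorm)
  gp <- gpp <- rep(NA_real_, nrow(vmap))
  reason <- character(nrow(vmap))
  for (i in seq_len(nrow(vmap))) {
    if (bnorm[i] < low_beta_cutoff * med) { reason[i] <- "low-beta"; next }
    if (isTRUE(vmap$clipped[i])) { reason[i] <- "boundary"; next }
    if (has_alpha && is.finite(vmap$alpha_x[i])) {
      al <- c(vmap$alpha_x[i], vmap$alpha_y[i])
      be <- c(vmap$beta_x[i], vmap$beta_y[i])
      den <- (sum(al^2) - sum(be^2))^2 + 4 * sum(al * be)^2
      if (den == 0) { reason[i] <- "degenerate"; next }
      g <- moduli_from_vectors(al, be, rho)
      gp[i] <- g[["Gp"]]; gpp[i] <- g[["Gpp"]]
    } else {
      gp[i] <- rho / bnorm[i]^2
    }
    if (!is.na(gp[i]) && gp[i] <= 0) { reason[i] <- "nonpositive-gp" }
  }
  out <- data.frame(x_m = vmap$x_m, y_m = vmap$y_m,
                    Gp_Pa = gp, Gpp_Pa = gpp,
                    valid = reason == "", reason = reason,
                    stringsAsFactors = FALSE)
  out$Gp_Pa[!out$valid & reason != "nonpositive-gp"] <- NA_real_
  attr(out, "rho") <- rho
  attr(out, "low_beta_cutoff") <- low_beta_cutoff
  class(out) <- c("moduli_map", "data.frame")
  out
}

#' Region-of-interest statistics of a moduli map
#'
#' Arithmetic mean and population (divide-by-N) standard deviation of the
#' unmasked values inside rectangular regions.
#'
#' @param mmap A [moduli_map()].
#' @param rois Named list of regions, each `list(xlim = c(min, max),
#'   ylim = c(min, max))` in meters.
#' @param quantity `"Gp"` or `"Gpp"`.
#' @return Data frame with one row per region: `region`, `quantity`,
#'   `mean_Pa`, `sd_Pa`, `n`.
#' @export
roi_stats <- function(mmap, rois, quantity = c("Gp", "Gpp")) {
  stopifnot(inherits(mmap, "moduli_map"), is.list(rois))
  quantity <- match.arg(quantity)
  col <- if (quantity == "Gp") "Gp_Pa" else "Gpp_Pa"
  if (is.null(names(rois)) || any(names(rois) == ""))
    stop("`rois` must be a named list")
  rows <- lapply(names(rois), function(nm) {
    r <- rois[[nm]]
    sel <- mmap$valid &
      mmap$x_m >= r$xlim[1] & mmap$x_m <= r$xlim[2] &
      mmap$y_m >= r$ylim[1] & mmap$y_m <= r$ylim[2] &
      !is.na(mmap[[col]])
    v <- mmap[[col]][sel]
    if (length(v) == 0L)
      stop(sprintf("region '%s' contains no unmasked sample points", nm))
    data.frame(region = nm, quantity = quantity,
               mean_Pa = mean(v),
               sd_Pa = sqrt(mean((v - mean(v))^2)),
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
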