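## Focused incident field for an annular condenser (Debye scalar model):
## direct closed-form series evaluation, and an optional circularly-symmetric
## cached cross-section (lookup table) exploiting the rotational symmetry of
## the focused beam about the optical axis (+z, light propagating toward +z).

#' Optical configuration for one wavelength
#'
#' Collects the wavelength, condenser annulus angles (from inner/outer
#' numerical apertures, \eqn{\alpha = \arcsin(NA)}), the complex amplitude
#' \eqn{E_0}, the focal point, and the partial-wave series order.
#'
#' @param lam Wavelength, micrometers.
#' @param na Condenser numerical apertures \code{c(inner, outer)}; a single
#'   value is taken as the outer NA with no obscuration.
#' @param E0 Complex scalar amplitude (default 1).
#' @param p_f Focal point, 3D micrometers.
#' @param order Series order; \code{NULL} defers to the evaluation radius
#'   (with a floor of 100 for sphere-free point-spread-function renders).
#' @return Object of class \code{optical_config} with fields \code{lam},
#'   \code{k}, \code{alpha1}, \code{alpha2}, \code{E0}, \code{p_f},
#'   \code{order}.
#' @export
optical_config <- function(lam, na = c(0, 0.62), E0 = 1 + 0i,
                           p_f = c(0, 0, 0), order = NULL) {
  stopifnot(length(lam) == 1L, lam > 0)
  if (length(na) == 1L) na <- c(0, na)
  stopifnot(length(na) == 2L)
  if (!(na[1] >= 0 && na[1] < na[2] && na[2] <= 1)) {
    stop("require 0 <= NA_inner < NA_outer <= 1")
  }
  if (!is.null(order)) {
    order <- as.integer(order)
    stopifnot(order >= 1L)
  }
  structure(list(lam = lam, k = 2 * pi / lam,
                 alpha1 = asin(na[1]), alpha2 = asin(na[2]),
                 na = na,
                 E0 = as.complex(E0), p_f = as.numeric(p_f), order = order),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("<optical_config> lambda = %.4g um, NA = [%.3g, %.3g], E0 = %s, order = %s\n",
              x$lam, x$na[1], x$na[2], format(x$E0),
              if (is.null(x$order)) "auto" else x$order))
  invisible(x)
}

#' Scalar plane wave
#'
#' \eqn{E(r) = E_0 e^{i k \hat{s} \cdot (r - p_f)}}; the phase is referenced
#' to the focal point so that all aperture plane waves interfere
#' constructively there.
#'
#' @param config An \code{optical_config}.
#' @param direction Propagation direction (unit 3-vector; normalized with a
#'   warning otherwise).
#' @param points n x 3 matrix of positions (micrometers).
#' @return Complex vector of field values.
#' @export
plane_wave <- function(config, direction, points) {
  stopifnot(inherits(config, "optical_config"))
  points <- as_points(points)
  nv <- vec_norm(direction)
  if (abs(nv - 1) > 1e-12) {
    warning("plane_wave: direction was not unit length; normalized")
    direction <- direction / nv
  }
  rel <- sweep(points, 2L, config$p_f)
  config$E0 * exp(1i * config$k * as.vector(rel %*% direction))
}

## Order needed to evaluate the partial-wave series out to radius r_max.
order_for_radius <- function(k, r_max) {
  x <- max(k * r_max, 1e-6)
  as.integer(ceiling(x + 4 * x^(1 / 3) + 2))
}

#' Focused incident field (closed form)
#'
#' Evaluates the annular-aperture focused field
#' \deqn{E_f(p) = 2\pi E_0 \sum_{l=0}^{L} i^l j_l(kr) P_l(\cos\theta)\, c_l}
#' with \eqn{r = |p - p_f|}, \eqn{\theta} the polar angle from the optical
#' axis (+z), and \eqn{c_l} the annulus coefficients
#' (\code{\link{aperture_coeffs}}). At the focal point this reduces to
#' \eqn{2\pi E_0(\cos\alpha_1 - \cos\alpha_2)}.
#'
#' @param config An \code{optical_config}. If \code{config$order} is set but
#'   too small for the largest evaluation radius, a truncation warning is
#'   issued.
#' @param points n x 3 matrix of positions (micrometers).
#' @return Complex vector of field values; deterministic.
#' @export
focused_field <- function(config, points) {
  stopifnot(inherits(config, "optical_config"))
  points <- as_points(points)
  rel <- sweep(points, 2L, config$p_f)
  r <- sqrt(rowSums(rel^2))
  costh <- ifelse(r > 0, rel[, 3] / r, 1)
  needed <- order_for_radius(config$k, max(r))
  if (is.null(config$order)) {
    L <- max(100L, needed)
  } else {
    L <- config$order
    if (L < needed) {
      warning(sprintf("focused_field: order %d below convergence order %d for the evaluation radius; series truncated",
                      L, needed))
    }
  }
  cl <- aperture_coeffs(L, config$alpha1, config$alpha2)
  il <- 1i^(0:L)
  out <- complex(length(r))
  ## chunk points to bound the (L+1) x n working matrices
  chunk <- max(1L, 2^21 %/% (L + 1L))
  for (s in split(seq_along(r), ceiling(seq_along(r) / chunk))) {
    jl <- sph_bessel_j_real(L, config$k * r[s])
    P <- legendre_sequence(L, costh[s])
    out[s] <- as.vector((il * cl) %*% (jl * P))
  }
  2 * pi * config$E0 * out
}

#' Cached cross-section of the circularly-symmetric focused field
#'
#' The annular condenser produces a field that is rotationally symmetric
#' about the optical axis and conjugate-symmetric (relative to the \eqn{E_0}
#' phase) across the focal plane, so a single quarter cross-section in
#' cylindrical coordinates (axial u >= 0, radial v >= 0) determines the
#' field everywhere between condenser and objective.
#'
#' @param config An \code{optical_config}.
#' @param u_range,v_range Axial and radial half-extents covered, micrometers.
#' @param R Samples per side of the table.
#' @return Object of class \code{incident_lut}.
#' @export
incident_lut <- function(config, u_range, v_range, R) {
  stopifnot(R >= 2L, u_range > 0, v_range > 0)
  u <- seq(0, u_range, length.out = R)
  v <- seq(0, v_range, length.out = R)
  g <- expand.grid(v = v, u = u)   # v varies fastest -> matrix [v, u]
  pts <- cbind(config$p_f[1] + g$v, config$p_f[2], config$p_f[3] + g$u)
  vals <- focused_field(config, pts) / config$E0
  structure(list(u = u, v = v,
                 table = matrix(vals, nrow = R, ncol = R),  # [v index, u index]
                 config = config),
            class = "incident_lut")
}

#' Sample the focused field from the cached cross-section
#'
#' Maps each 3D point to cylindrical coordinates about the optical axis
#' through the focal point, bilinearly interpolates the stored quarter
#' cross-section, and applies the conjugate mirror for points on the
#' negative axial side. Queries outside the table range clamp with a
#' warning.
#'
#' @param lut An \code{incident_lut}.
#' @param points n x 3 matrix of positions.
#' @return Complex field values.
#' @export
sample_incident_lut <- function(lut, points) {
  stopifnot(inherits(lut, "incident_lut"))
  points <- as_points(points)
  cfg <- lut$config
  rel <- sweep(points, 2L, cfg$p_f)
  uq <- rel[, 3]
  vq <- sqrt(rel[, 1]^2 + rel[, 2]^2)
  mirror <- uq < 0
  uq <- abs(uq)
  if (any(uq > max(lut$u) + 1e-9) || any(vq > max(lut$v) + 1e-9)) {
    warning("sample_incident_lut: query outside table range; clamped")
  }
  vals <- bilinear_complex(lut$u, lut$v, lut$table, uq, vq)
  vals[mirror] <- Conj(vals[mirror])
  cfg$E0 * vals
}

## Bilinear interpolation on a complex table[v_index, u_index] with clamping.
bilinear_complex <- function(u_axis, v_axis, tab, uq, vq) {
  clampi <- function(axis, q) {
    q <- pmin(max(axis), pmax(min(axis), q))
    step <- axis[2] - axis[1]
    i0 <- pmin(length(axis) - 1L, pmax(1L, floor((q - axis[1]) / step) + 1L))
    t <- (q - axis[i0]) / step
    list(i0 = i0, t = pmin(1, pmax(0, t)))
  }
  au <- clampi(u_axis, uq)
  av <- clampi(v_axis, vq)
  n_v <- length(v_axis)
  idx <- function(iv, iu) (iu - 1L) * n_v + iv
  v00 <- tab[idx(av$i0, au$i0)]
  v10 <- tab[idx(av$i0 + 1L, au$i0)]
  v01 <- tab[idx(av$i0, au$i0 + 1L)]
  v11 <- tab[idx(av$i0 + 1L, au$i0 + 1L)]
  (1 - au$t) * ((1 - av$t) * v00 + av$t * v10) +
    au$t * ((1 - av$t) * v01 + av$t * v11)
}
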