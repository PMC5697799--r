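## Per-sphere Mie scattering: partial-wave coefficients, single-plane-wave
## internal/external fields with the off-focus phase shift, scatter-domain
## lookup tables, stratified Monte-Carlo aperture integration, superposition
## into the total field, and sphere-surface field meshes.

#' Construct a sphere
#'
#' @param center Sphere center \eqn{p_s}, 3D micrometers.
#' @param radius Radius \eqn{a}, micrometers, > 0.
#' @param material A \code{material_spectrum}, or a single complex refractive
#'   index used at every wavelength.
#' @return Object of class \code{mie_sphere}.
#' @export
sphere <- function(center, radius, material) {
  stopifnot(length(center) == 3L, radius > 0)
  if (is.numeric(material) || is.complex(material)) {
    stopifnot(length(material) == 1L)
    n <- as.complex(material)
    if (Im(n) < 0) stop("extinction (Im n) must be >= 0")
    material <- material_spectrum(1, Re(n), Im(n), n0 = Re(n))
    ## single-sample spectrum: constant in wavelength
  }
  stopifnot(inherits(material, "material_spectrum"))
  structure(list(center = as.numeric(center), radius = radius,
                 material = material),
            class = "mie_sphere")
}

## Warn (once) about overlapping spheres in a scene.
check_sphere_overlap <- function(spheres) {
  ns <- length(spheres)
  if (ns < 2L) return(invisible(NULL))
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      d <- vec_norm(spheres[[i]]$center - spheres[[j]]$center)
      if (d < spheres[[i]]$radius + spheres[[j]]$radius) {
        warning(sprintf("spheres %d and %d overlap (center distance %.4g < radii sum %.4g)",
                        i, j, d, spheres[[i]]$radius + spheres[[j]]$radius))
      }
    }
  }
  invisible(NULL)
}

#' Mie scattering coefficients for a homogeneous sphere
#'
#' Per-order complex weights coupling the incident partial-wave expansion to
#' the external scattered series (\eqn{B_l}, propagating via
#' \eqn{h^{(1)}_l(kr)}) and the internal series (\eqn{A_l}, via
#' \eqn{j_l(knr)}):
#' \deqn{B_l = (2l+1) i^l \frac{j_l(ka) j'_l(kna)\,n - j_l(kna) j'_l(ka)}
#'   {j_l(kna) h^{(1)\prime}_l(ka) - h^{(1)}_l(ka) j'_l(kna)\, n}}
#' \deqn{A_l = (2l+1) i^l \frac{j_l(ka) h^{(1)\prime}_l(ka) - j'_l(ka) h^{(1)}_l(ka)}
#'   {j_l(kna) h^{(1)\prime}_l(ka) - h^{(1)}_l(ka) j'_l(kna)\, n}}
#' The order runs to the Bohren--Huffman convergence bound
#' (\code{\link{max_order}}); if the trailing coefficient has not decayed to
#' \eqn{10^{-6}} of the peak the order is raised automatically.
#'
#' @param a Radius, micrometers.
#' @param n Complex refractive index at this wavelength (Im(n) >= 0).
#' @param lam Wavelength, micrometers.
#' @param l_max Optional order override.
#' @return Object of class \code{scattering_coefficients} with fields
#'   \code{A}, \code{B} (length l_max + 1), \code{lam}, \code{n}, \code{a},
#'   \code{l_max}.
#' @export
scattering_coefficients <- function(a, n, lam, l_max = NULL) {
  stopifnot(a > 0, lam > 0)
  n <- as.complex(n)
  if (Im(n) < 0) stop("Im(n) must be >= 0")
  L <- if (is.null(l_max)) max_order(a, lam) else as.integer(l_max)
  auto <- is.null(l_max)
  k <- 2 * pi / lam
  for (attempt in 1:8) {
    ext <- spherical_bessel_family(L, k * a)
    int <- if (Im(n) == 0) spherical_bessel_family(L, Re(n) * k * a)
           else spherical_bessel_family(L, n * k * a)
    jka <- ext$j[, 1]; djka <- ext$dj[, 1]
    hka <- ext$h1[, 1]; dhka <- ext$dh1[, 1]
    jna <- int$j[, 1]; djna <- int$dj[, 1]
    denom <- jna * dhka - hka * djna * n
    if (any(abs(denom) < 1e-300)) {
      bad <- which(abs(denom) < 1e-300)[1] - 1L
      stop(sprintf("vanishing Mie denominator at l = %d (ka = %.6g, n = %s): resonance at numerical precision",
                   bad, k * a, format(n)))
    }
    pref <- (2 * (0:L) + 1) * 1i^(0:L)
    B <- pref * (jka * djna * n - jna * djka) / denom
    A <- pref * (jka * dhka - djka * hka) / denom
    if (!auto) break
    ## Convergence check on the surface series terms |B_l h1_l(ka)| and
    ## |A_l j_l(kna)| (the per-order field magnitudes that bound the
    ## truncation error; for B this coincides with coefficient decay, and
    ## unlike raw |A_l| it remains meaningful as n -> 1).
    tB <- abs(B * hka)
    tA <- abs(A * jna)
    ok <- function(t) max(t) == 0 || t[L + 1L] < 1e-6 * max(t)
    if (ok(tB) && ok(tA) && abs(B[L + 1L]) <= 1e-6 * max(abs(B))) break
    L <- as.integer(ceiling(L * 1.25) + 4L)
  }
  structure(list(A = A, B = B, lam = lam, n = n, a = a, l_max = L),
            class = "scattering_coefficients")
}

#' @export
print.scattering_coefficients <- function(x, ...) {
  cat(sprintf("<scattering_coefficients> a = %.4g um, lambda = %.4g um, n = %s, l_max = %d\n",
              x$a, x$lam, format(x$n), x$l_max))
  invisible(x)
}

## Order-weighted radial factors for a set of radii about the sphere center:
## rows l = 0..l_max of B_l h1_l(kr) (external, r > 0) or A_l j_l(knr)
## (internal). Returned as (l_max+1) x length(r) complex matrices.
radial_weights_external <- function(coeffs, r) {
  k <- 2 * pi / coeffs$lam
  fam <- spherical_bessel_family(coeffs$l_max, k * r)
  fam$h1 * coeffs$B
}

radial_weights_internal <- function(coeffs, r) {
  k <- 2 * pi / coeffs$lam
  kn <- k * coeffs$n
  z <- kn * r
  j <- if (Im(coeffs$n) == 0) sph_bessel_j_complex_or_real(coeffs$l_max, Re(z))
       else sph_bessel_j_complex(coeffs$l_max, z)
  j * coeffs$A
}

sph_bessel_j_complex_or_real <- function(l_max, x) {
  sph_bessel_j_real(l_max, x) + 0i
}

## Accumulate sum_l W[l+1, ] * P_l(costh) with a running Legendre
## recurrence; W is (l_max+1) x n, costh length n.
legendre_contract <- function(W, costh) {
  L <- nrow(W) - 1L
  acc <- W[1L, ]
  if (L >= 1L) {
    p_prev <- rep(1, length(costh))
    p_cur <- costh
    acc <- acc + W[2L, ] * p_cur
    if (L >= 2L) {
      for (l in 2:L) {
        p_new <- ((2 * l - 1) * costh * p_cur - (l - 1) * p_prev) / l
        acc <- acc + W[l + 1L, ] * p_new
        p_prev <- p_cur
        p_cur <- p_new
      }
    }
  }
  acc
}

#' Field of a sphere under a single incident plane wave
#'
#' Evaluates the external scattered series (for \eqn{r \ge a}) or the
#' internal total series (for \eqn{r < a}), including the off-focus phase
#' factor \eqn{e^{i k\, \hat{s} \cdot c}} with \eqn{c = p_s - p_f}:
#' \deqn{E_s(p) = e^{ik\hat{s}\cdot c}\sum_l B_l h^{(1)}_l(kr) P_l(\cos\theta)}
#' \deqn{E_i(p) = e^{ik\hat{s}\cdot c}\sum_l A_l j_l(knr) P_l(\cos\theta)}
#' where \eqn{\cos\theta = \hat{s}\cdot(p - p_s)/r}. The external value
#' excludes the incident plane wave itself. Points on the surface (within
#' \eqn{10^{-9} a}) evaluate the internal branch; the two branches agree
#' there by construction.
#'
#' @param sph A \code{mie_sphere}.
#' @param coeffs Matching \code{scattering_coefficients}.
#' @param direction Unit propagation direction \eqn{\hat{s}}.
#' @param p_f Focal point (phase reference), 3D micrometers.
#' @param points n x 3 positions.
#' @return Complex field values.
#' @export
planewave_sphere_field <- function(sph, coeffs, direction, p_f = c(0, 0, 0),
                                   points) {
  stopifnot(inherits(sph, "mie_sphere"),
            inherits(coeffs, "scattering_coefficients"))
  points <- as_points(points)
  nv <- vec_norm(direction)
  if (abs(nv - 1) > 1e-12) {
    warning("planewave_sphere_field: direction normalized")
    direction <- direction / nv
  }
  k <- 2 * pi / coeffs$lam
  rel <- sweep(points, 2L, sph$center)
  r <- sqrt(rowSums(rel^2))
  costh <- ifelse(r > 0, as.vector(rel %*% direction) / r, 1)
  inside <- r <= sph$radius * (1 + 1e-9)
  out <- complex(length(r))
  if (any(inside)) {
    W <- radial_weights_internal(coeffs, r[inside])
    out[inside] <- legendre_contract(W, costh[inside])
  }
  if (any(!inside)) {
    W <- radial_weights_external(coeffs, r[!inside])
    out[!inside] <- legendre_contract(W, costh[!inside])
  }
  phase <- exp(1i * k * sum(direction * (sph$center - p_f)))
  phase * out
}

#' Scatter-domain lookup tables
#'
#' Tabulates the un-phase-shifted single-plane-wave field of a sphere over
#' (distance from center \eqn{d}, \eqn{\cos\theta}): an external table for
#' \eqn{d \ge a} and an internal table for \eqn{d \le a}. The angular
#' resolution must satisfy the Nyquist rule \eqn{R_\theta \ge 2 N_l} for the
#' highest-order Legendre oscillations.
#'
#' @param sph A \code{mie_sphere}.
#' @param coeffs Matching \code{scattering_coefficients}.
#' @param fov Field of view, micrometers; distances run to fov/2.
#' @param R Radial samples of the external table.
#' @param R_theta Angular samples over cos(theta) in [-1, 1] (default 1000).
#' @return Object of class \code{scatter_domain}.
#' @export
scatter_domain <- function(sph, coeffs, fov, R, R_theta = 1000L) {
  stopifnot(fov / 2 > sph$radius, R >= 2L)
  if (R_theta < 2L * coeffs$l_max) {
    warning(sprintf("R_theta = %d below the Nyquist bound 2*N_l = %d; interpolation will alias",
                    R_theta, 2L * coeffs$l_max))
  }
  costh <- seq(-1, 1, length.out = R_theta)
  P <- legendre_sequence(coeffs$l_max, costh)
  d_ext <- seq(sph$radius, fov / 2, length.out = R)
  n_int <- max(2L, as.integer(ceiling(R * sph$radius / (fov / 2))))
  d_int <- seq(0, sph$radius, length.out = n_int)
  Wext <- radial_weights_external(coeffs, d_ext)
  Wint <- radial_weights_internal(coeffs, d_int)
  structure(list(d_ext = d_ext, d_int = d_int, costh = costh,
                 external = t(Wext) %*% P,   # R x R_theta
                 internal = t(Wint) %*% P,
                 a = sph$radius, fov = fov, l_max = coeffs$l_max),
            class = "scatter_domain")
}

#' Sample a scatter domain
#'
#' Bilinear interpolation of the tabulated single-plane-wave field at
#' (d, cos theta). The caller applies any off-focus phase factor. Distances
#' beyond fov/2 clamp with a warning; the internal table is used for
#' \eqn{d \le a}.
#'
#' @param domain A \code{scatter_domain}.
#' @param d Distances from the sphere center.
#' @param costheta Cosines of the angle to the propagation direction.
#' @return Complex field values.
#' @export
sample_scatter_domain <- function(domain, d, costheta) {
  stopifnot(inherits(domain, "scatter_domain"))
  stopifnot(length(d) == length(costheta) || length(d) == 1L || length(costheta) == 1L)
  n <- max(length(d), length(costheta))
  d <- rep_len(d, n); costheta <- rep_len(costheta, n)
  if (any(d > domain$fov / 2 + 1e-9)) {
    warning("sample_scatter_domain: d beyond fov/2; clamped")
  }
  out <- complex(n)
  inside <- d <= domain$a
  if (any(inside)) {
    out[inside] <- bilinear_complex(domain$d_int, domain$costh,
                                    t(domain$internal), d[inside], costheta[inside])
  }
  if (any(!inside)) {
    out[!inside] <- bilinear_complex(domain$d_ext, domain$costh,
                                     t(domain$external), d[!inside], costheta[!inside])
  }
  out
}

#' Stratified Monte-Carlo samples of an annular aperture
#'
#' Jittered stratified sampling, uniform on the spherical annulus via
#' Archimedes' projection: uniform in \eqn{(\phi, z)} over
#' \eqn{[0, 2\pi] \times [\cos\alpha_2, \cos\alpha_1]}, mapped to unit
#' vectors \eqn{(\sqrt{1-z^2}\cos\phi, \sqrt{1-z^2}\sin\phi, z)}.
#' Deterministic for a given seed; the caller's RNG state is untouched.
#'
#' @param alpha1,alpha2 Annulus angles, radians, 0 <= alpha1 < alpha2.
#' @param M Number of samples, >= 1.
#' @param seed Integer seed.
#' @param stratify Jittered stratified sampling (default) versus plain
#'   uniform sampling. Stratification reduces the integration error decay
#'   from the textbook \eqn{M^{-1/2}} to roughly \eqn{M^{-1}} for smooth
#'   aperture integrands.
#' @return Object of class \code{mc_sampling} with the M x 3 direction
#'   matrix.
#' @export
aperture_samples <- function(alpha1, alpha2, M, seed = 1L, stratify = TRUE) {
  stopifnot(M >= 1L, alpha1 >= 0, alpha1 < alpha2, alpha2 <= pi)
  M <- as.integer(M)
  z_lo <- cos(alpha2); z_hi <- cos(alpha1)
  uv <- with_seed(seed, {
    if (stratify) {
      n_z <- max(1L, as.integer(floor(sqrt(M))))
      n_phi <- M %/% n_z
      base <- n_z * n_phi
      gz <- (rep(seq_len(n_z), each = n_phi) - 1L + stats::runif(base)) / n_z
      gp <- (rep(seq_len(n_phi), times = n_z) - 1L + stats::runif(base)) / n_phi
      if (base < M) {
        gz <- c(gz, stats::runif(M - base))
        gp <- c(gp, stats::runif(M - base))
      }
      cbind(gp, gz)
    } else {
      cbind(stats::runif(M), stats::runif(M))
    }
  })
  phi <- 2 * pi * uv[, 1]
  z <- z_lo + (z_hi - z_lo) * uv[, 2]
  s <- sqrt(pmax(0, 1 - z^2))
  structure(list(M = M, seed = as.integer(seed),
                 alpha1 = alpha1, alpha2 = alpha2,
                 directions = cbind(s * cos(phi), s * sin(phi), z)),
            class = "mc_sampling")
}

#' Monte-Carlo estimate of a sphere's aperture-integrated field
#'
#' Averages the single-plane-wave solution over the stratified aperture
#' directions with the solid-angle weight:
#' \deqn{E \approx \frac{2\pi E_0[(1-\cos\alpha_2) - (1-\cos\alpha_1)]}{M}
#'   \sum_{j=1}^{M} E(p, \hat{k}_j)}
#' Internal points receive the internal series, external points the
#' scattered series (excluding the focused incident field, which the caller
#' adds via \code{\link{focused_field}}).
#'
#' @param sph A \code{mie_sphere}.
#' @param coeffs Matching \code{scattering_coefficients}.
#' @param sampling An \code{mc_sampling} drawn for the same aperture as
#'   \code{config}.
#' @param config An \code{optical_config}.
#' @param points n x 3 positions.
#' @param domain Optional \code{scatter_domain} accelerator; when supplied,
#'   per-sample fields are interpolated from the table instead of direct
#'   series evaluation.
#' @return Complex field values (stochastic, seed-reproducible).
#' @export
mc_sphere_field <- function(sph, coeffs, sampling, config, points,
                            domain = NULL) {
  stopifnot(inherits(sampling, "mc_sampling"), inherits(config, "optical_config"))
  if (abs(sampling$alpha1 - config$alpha1) > 1e-9 ||
      abs(sampling$alpha2 - config$alpha2) > 1e-9) {
    warning("mc_sphere_field: sampling aperture differs from config aperture")
  }
  points <- as_points(points)
  k <- config$k
  rel <- sweep(points, 2L, sph$center)
  r <- sqrt(rowSums(rel^2))
  inside <- r <= sph$radius * (1 + 1e-9)
  cvec <- sph$center - config$p_f
  dirs <- sampling$directions
  acc <- complex(length(r))
  if (is.null(domain)) {
    Wint <- if (any(inside)) radial_weights_internal(coeffs, r[inside]) else NULL
    Wext <- if (any(!inside)) radial_weights_external(coeffs, r[!inside]) else NULL
    for (jj in seq_len(sampling$M)) {
      s_hat <- dirs[jj, ]
      phase <- exp(1i * k * sum(s_hat * cvec))
      costh <- ifelse(r > 0, as.vector(rel %*% s_hat) / r, 1)
      val <- complex(length(r))
      if (!is.null(Wint)) val[inside] <- legendre_contract(Wint, costh[inside])
      if (!is.null(Wext)) val[!inside] <- legendre_contract(Wext, costh[!inside])
      acc <- acc + phase * val
    }
  } else {
    for (jj in seq_len(sampling$M)) {
      s_hat <- dirs[jj, ]
      phase <- exp(1i * k * sum(s_hat * cvec))
      costh <- ifelse(r > 0, as.vector(rel %*% s_hat) / r, 1)
      acc <- acc + phase * sample_scatter_domain(domain, r, costh)
    }
  }
  pref <- 2 * pi * config$E0 * (cos(config$alpha1) - cos(config$alpha2)) / sampling$M
  pref * acc
}

#' Total field of a scene
#'
#' Single-scattering (first Born) superposition: inside a sphere the field
#' is that sphere's Monte-Carlo internal field; outside all spheres it is
#' the focused incident field plus the sum of every sphere's Monte-Carlo
#' scattered field. Spheres do not re-scatter each other's fields. One
#' shared direction set is used for all spheres, preserving inter-sphere
#' coherence.
#'
#' @param config An \code{optical_config}.
#' @param spheres List of \code{mie_sphere} objects (possibly empty).
#' @param sampling An \code{mc_sampling}; may be \code{NULL} when
#'   \code{spheres} is empty.
#' @param points n x 3 positions.
#' @param coeffs_list Optional pre-computed coefficients per sphere.
#' @return Complex field values.
#' @export
total_field <- function(config, spheres, sampling, points, coeffs_list = NULL) {
  points <- as_points(points)
  ## a sphere with n = 1 at this wavelength is optically absent: drop it so
  ## the null-scatterer identity (total field == focused field) is exact
  null_sph <- vapply(spheres, function(s) {
    abs(material_at(s$material, config$lam) - 1) < 1e-14
  }, logical(1))
  spheres <- spheres[!null_sph]
  if (!is.null(coeffs_list)) coeffs_list <- coeffs_list[!null_sph]
  if (length(spheres) == 0L) return(focused_field(config, points))
  check_sphere_overlap(spheres)
  if (is.null(coeffs_list)) {
    coeffs_list <- lapply(spheres, function(s) {
      scattering_coefficients(s$radius, material_at(s$material, config$lam),
                              config$lam)
    })
  }
  inside_mat <- vapply(spheres, function(s) {
    rel <- sweep(points, 2L, s$center)
    sqrt(rowSums(rel^2)) <= s$radius * (1 + 1e-9)
  }, logical(nrow(points)))
  inside_mat <- matrix(inside_mat, nrow = nrow(points))
  n_in <- rowSums(inside_mat)
  if (any(n_in > 1L)) {
    stop("total_field: point(s) inside two spheres (overlapping scene)")
  }
  out <- complex(nrow(points))
  outside <- n_in == 0L
  if (any(outside)) {
    out[outside] <- focused_field(config, points[outside, , drop = FALSE])
    for (si in seq_along(spheres)) {
      out[outside] <- out[outside] +
        mc_sphere_field(spheres[[si]], coeffs_list[[si]], sampling, config,
                        points[outside, , drop = FALSE])
    }
  }
  for (si in seq_along(spheres)) {
    sel <- inside_mat[, si]
    if (any(sel)) {
      out[sel] <- mc_sphere_field(spheres[[si]], coeffs_list[[si]], sampling,
                                  config, points[sel, , drop = FALSE])
    }
  }
  out
}

#' Field on a sphere's surface as a triangulated mesh
#'
#' Evaluates the total scene field at the vertices of a subdivided
#' icosahedron scaled to the sphere radius (42, 162, 642, ... vertices).
#' Surface vertices evaluate the internal branch; internal and external
#' series agree there by construction.
#'
#' @param sph The sphere whose surface is meshed.
#' @param config An \code{optical_config}.
#' @param spheres Full scene sphere list (the mesh sphere included).
#' @param sampling An \code{mc_sampling}.
#' @param n_vertices One of 12, 42, 162, 642, 2562 (icosphere subdivisions).
#' @return Object of class \code{surface_mesh}: \code{vertices} (V x 3),
#'   \code{faces} (F x 3, 1-based), \code{values} (complex),
#'   \code{magnitude}.
#' @export
surface_field <- function(sph, config, spheres = list(sph), sampling,
                          n_vertices = 162L) {
  counts <- c(12L, 42L, 162L, 642L, 2562L)
  if (!n_vertices %in% counts) {
    stop("n_vertices must be one of ", paste(counts, collapse = ", "))
  }
  ico <- icosphere(which(counts == n_vertices) - 1L)
  verts <- ico$vertices * sph$radius
  verts <- sweep(verts, 2L, sph$center, `+`)
  vals <- total_field(config, spheres, sampling, verts)
  structure(list(vertices = verts, faces = ico$faces, values = vals,
                 magnitude = Mod(vals), sphere = sph),
            class = "surface_mesh")
}

#' Unit icosphere by recursive subdivision
#'
#' @param subdiv Number of 4-to-1 triangle subdivisions (0 = icosahedron).
#' @return List with \code{vertices} (V x 3 on the unit sphere) and
#'   \code{faces} (F x 3, 1-based).
#' @export
icosphere <- function(subdiv = 2L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- edge_mid[[key]]
      if (!is.null(m)) return(m)
      p <- vlist[[i]] + vlist[[j]]
      p <- p / sqrt(sum(p^2))
      vlist[[length(vlist) + 1L]] <<- p
      idx <- length(vlist)
      edge_mid[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (fi in seq_len(nrow(f))) {
      a <- f[fi, 1]; b <- f[fi, 2]; cc <- f[fi, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4L * fi - 3L, ] <- c(a, ab, ca)
      nf[4L * fi - 2L, ] <- c(b, bc, ab)
      nf[4L * fi - 1L, ] <- c(cc, ca, bc)
      nf[4L * fi, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  list(vertices = v, faces = f)
}
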