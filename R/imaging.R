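## Fourier-optics image formation: objective band-pass filtering of a
## focal-plane field slice, detector intensity with block resampling,
## absorbance images, per-pixel spectra, and extended incoherent sources.

#' Construct a planar field slice
#'
#' A square R x R grid of complex scalar samples on the plane spanned by two
#' orthonormal in-plane axes. Sample (i, j) sits at
#' \code{origin + ((i - 1/2)/R - 1/2) S axis_u + ((j - 1/2)/R - 1/2) S axis_v}
#' (pixel centers).
#'
#' @param origin Slice center, 3D micrometers.
#' @param axis_u,axis_v Orthonormal in-plane direction vectors.
#' @param extent Side length S, micrometers.
#' @param R Samples per side (>= 2).
#' @param samples Optional R x R complex matrix of field values.
#' @return Object of class \code{field_slice}.
#' @export
field_slice <- function(origin = c(0, 0, 0), axis_u = c(1, 0, 0),
                        axis_v = c(0, 1, 0), extent, R, samples = NULL) {
  R <- as.integer(R)
  stopifnot(R >= 2L, extent > 0)
  if (abs(vec_norm(axis_u) - 1) > 1e-9 || abs(vec_norm(axis_v) - 1) > 1e-9) {
    stop("slice axes must be unit length")
  }
  if (abs(sum(axis_u * axis_v)) > 1e-9) stop("slice axes must be orthogonal")
  if (!is.null(samples)) {
    samples <- as.matrix(samples)
    stopifnot(nrow(samples) == R, ncol(samples) == R)
    if (!is.complex(samples)) samples <- samples + 0i
  }
  structure(list(origin = as.numeric(origin), axis_u = as.numeric(axis_u),
                 axis_v = as.numeric(axis_v), extent = extent, R = R,
                 samples = samples),
            class = "field_slice")
}

#' Sample positions of a field slice
#'
#' @param slice A \code{field_slice}.
#' @return (R^2) x 3 matrix of positions, u index varying fastest (matching
#'   column-major fill of the R x R sample matrix, samples[i, j] = u_i, v_j).
#' @export
slice_points <- function(slice) {
  stopifnot(inherits(slice, "field_slice"))
  R <- slice$R
  offs <- ((seq_len(R) - 0.5) / R - 0.5) * slice$extent
  g <- expand.grid(u = offs, v = offs)
  t(slice$origin + t(outer(g$u, slice$axis_u) + outer(g$v, slice$axis_v)))
}

#' Render a scene onto a field slice
#'
#' Fills the slice samples with \code{\link{total_field}} values.
#'
#' @param slice A \code{field_slice} (geometry only).
#' @param config An \code{optical_config}.
#' @param spheres List of spheres (possibly empty).
#' @param sampling An \code{mc_sampling} (unused when no spheres).
#' @param coeffs_list Optional pre-computed coefficients.
#' @return The slice with \code{samples} filled.
#' @export
render_slice <- function(slice, config, spheres = list(), sampling = NULL,
                         coeffs_list = NULL) {
  pts <- slice_points(slice)
  vals <- total_field(config, spheres, sampling, pts, coeffs_list)
  slice$samples <- matrix(vals, nrow = slice$R, ncol = slice$R)
  slice
}

#' Detector / objective configuration
#'
#' @param na_o Objective outer numerical aperture (0 < NA_o <= 1).
#' @param na_in Objective inner (obscuration) NA, 0 <= NA_in < NA_o.
#' @param S Field of view, micrometers.
#' @param R Field resolution (samples per side).
#' @param det_pixels Detector samples per side; must divide R.
#' @return Object of class \code{detector_config}.
#' @export
detector_config <- function(na_o, na_in = 0, S, R, det_pixels = R) {
  R <- as.integer(R); det_pixels <- as.integer(det_pixels)
  if (!(na_in >= 0 && na_in < na_o && na_o <= 1)) {
    stop("require 0 <= NA_in < NA_o <= 1")
  }
  if (det_pixels > R || R %% det_pixels != 0L) {
    divs <- Filter(function(d) R %% d == 0L, seq_len(R))
    stop(sprintf("det_pixels (%d) must divide R (%d); nearest valid: %d",
                 det_pixels, R,
                 divs[which.min(abs(divs - det_pixels))]))
  }
  structure(list(na_o = na_o, na_in = na_in, S = S, R = R,
                 det_pixels = det_pixels),
            class = "detector_config")
}

## Signed spatial frequencies of an R-point FFT with sample spacing S/R:
## frequency step 1/S, indices 0..R-1 mapped to 0..R/2, -(R/2-1)..-1.
fft_freqs <- function(R, S) {
  idx <- 0:(R - 1L)
  ifelse(idx > R %/% 2, idx - R, idx) / S
}

#' Objective band-pass filter of a field slice
#'
#' Fourier-optics transfer of an annular objective: the slice is Fourier
#' transformed, frequency components with radial frequency above
#' \eqn{f_u = NA_o/\lambda} or below \eqn{f_l = NA_{in}/\lambda} are
#' removed (boundary frequencies equal to a cutoff pass), and the field is
#' transformed back. Frequency steps are \eqn{\Delta u = \Delta v = 1/S}.
#'
#' @param slice A \code{field_slice} with samples.
#' @param det A \code{detector_config} matching the slice geometry.
#' @param lam Wavelength, micrometers.
#' @return The filtered \code{field_slice}.
#' @export
objective_bandpass <- function(slice, det, lam) {
  stopifnot(inherits(slice, "field_slice"), inherits(det, "detector_config"))
  if (is.null(slice$samples)) stop("slice has no samples")
  if (slice$R != det$R || abs(slice$extent - det$S) > 1e-9) {
    stop("slice geometry does not match detector configuration")
  }
  f_u <- det$na_o / lam
  f_l <- det$na_in / lam
  fr <- fft_freqs(slice$R, slice$extent)
  rad <- sqrt(outer(fr^2, fr^2, `+`))
  tol <- 1e-12 * max(f_u, 1)
  mask <- (rad <= f_u + tol) & (rad >= f_l - tol)
  Fhat <- stats::fft(slice$samples)
  slice$samples <- stats::fft(Fhat * mask, inverse = TRUE) / slice$R^2
  slice
}

#' Detector intensity image
#'
#' Squared magnitude of the (filtered) field at full resolution,
#' block-averaged to the detector pixel grid (mean over each pixel
#' footprint, preserving total flux).
#'
#' @param filtered A \code{field_slice}.
#' @param det A \code{detector_config}.
#' @return Object of class \code{mie_image} with fields \code{values},
#'   \code{pixel_size}, \code{kind = "intensity"}.
#' @export
detector_image <- function(filtered, det) {
  stopifnot(inherits(filtered, "field_slice"), inherits(det, "detector_config"))
  if (is.null(filtered$samples)) stop("slice has no samples")
  I <- Mod(filtered$samples)^2
  b <- det$R %/% det$det_pixels
  if (b > 1L) {
    ## block mean via grouped row/col sums
    grp <- rep(seq_len(det$det_pixels), each = b)
    I <- rowsum(I, grp) / b
    I <- t(rowsum(t(I), grp) / b)
    dimnames(I) <- NULL
  }
  structure(list(values = I, pixel_size = det$S / det$det_pixels,
                 kind = "intensity", mask = NULL),
            class = "mie_image")
}

#' @export
print.mie_image <- function(x, ...) {
  cat(sprintf("<mie_image> %s, %d x %d px (%.3g um/px), range [%.4g, %.4g]\n",
              x$kind, nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Absorbance image
#'
#' \eqn{A = -\log_{10}(I/I_0)} per pixel, where \eqn{I_0} is the intensity
#' image of the identical configuration with no spheres. Pixels where
#' \eqn{I_0} falls below \eqn{10^{-12} \max I_0} are flagged invalid in the
#' \code{mask} (and set NA), not given sentinel values.
#'
#' @param I Intensity image with spheres.
#' @param I0 Reference intensity image without spheres (same geometry).
#' @return A \code{mie_image} of kind \code{"absorbance"} with logical
#'   \code{mask} (TRUE = valid).
#' @export
absorbance_image <- function(I, I0) {
  stopifnot(inherits(I, "mie_image"), inherits(I0, "mie_image"))
  if (!all(dim(I$values) == dim(I0$values)) ||
      abs(I$pixel_size - I0$pixel_size) > 1e-12) {
    stop("absorbance_image: geometry mismatch between I and I0")
  }
  valid <- I0$values > 1e-12 * max(I0$values)
  A <- matrix(NA_real_, nrow(I$values), ncol(I$values))
  A[valid] <- -log10(I$values[valid] / I0$values[valid])
  structure(list(values = A, pixel_size = I$pixel_size,
                 kind = "absorbance", mask = valid),
            class = "mie_image")
}

## One coherent pipeline pass at a single wavelength: focal-plane slice ->
## objective band-pass -> intensity image. p_f_offset displaces the focal
## point laterally (extended sources).
simulate_intensity <- function(lam, na_cond, E0, spheres, det, mc_samples,
                               seed, order = NULL, p_f_offset = c(0, 0, 0),
                               with_spheres = TRUE) {
  cfg <- optical_config(lam, na = na_cond, E0 = E0,
                        p_f = c(p_f_offset[1], p_f_offset[2], p_f_offset[3]),
                        order = order)
  sampling <- if (length(spheres) && with_spheres) {
    aperture_samples(cfg$alpha1, cfg$alpha2, mc_samples, seed)
  } else NULL
  sl <- field_slice(origin = c(0, 0, 0), extent = det$S, R = det$R)
  sl <- render_slice(sl, cfg, if (with_spheres) spheres else list(), sampling)
  sl <- objective_bandpass(sl, det, lam)
  detector_image(sl, det)
}

#' Absorbance spectrum at a detector pixel
#'
#' Runs the full pipeline (material lookup, coefficients, fields, objective
#' filtering, detector) per wavelength and extracts the absorbance at one
#' pixel. The series order is re-derived from the convergence bound at each
#' wavelength. Material tables not covering a wavelength clamp to their
#' nearest endpoint.
#'
#' @param scene A \code{simulation_config} (see
#'   \code{\link{simulation_config}}).
#' @param det A \code{detector_config}; defaults to the scene's detector.
#' @param pixel Integer pair (row, column) in the detector grid; defaults to
#'   the center pixel.
#' @param wavelengths Wavelength list, micrometers; defaults to the scene's.
#' @return Data frame with columns \code{wavelength}, \code{absorbance}.
#' @export
point_spectrum <- function(scene, det = NULL, pixel = NULL, wavelengths = NULL) {
  stopifnot(inherits(scene, "simulation_config"))
  det <- det %||% scene$det
  wavelengths <- wavelengths %||% scene$wavelengths
  pixel <- pixel %||% rep(det$det_pixels %/% 2L + 1L, 2L)
  stopifnot(all(pixel >= 1L), all(pixel <= det$det_pixels))
  absorb <- vapply(wavelengths, function(lam) {
    I <- simulate_intensity(lam, scene$na_cond, scene$E0, scene$spheres, det,
                            scene$mc_samples, scene$seed, scene$order)
    I0 <- simulate_intensity(lam, scene$na_cond, scene$E0, scene$spheres, det,
                             scene$mc_samples, scene$seed, scene$order,
                             with_spheres = FALSE)
    A <- absorbance_image(I, I0)
    A$values[pixel[1], pixel[2]]
  }, numeric(1))
  data.frame(wavelength = wavelengths, absorbance = absorb)
}

#' Extended (incoherent) source image
#'
#' Simulates an extended source as a weighted incoherent sum of laterally
#' displaced point sources: for each source-map sample with positive weight
#' the coherent pipeline is run with the focal point displaced by the
#' sample's offset, and the resulting intensity images are averaged with
#' the sample weights. Absorbance uses the matching extended-source
#' reference.
#'
#' @param scene A \code{simulation_config}.
#' @param det A \code{detector_config}; defaults to the scene's.
#' @param source_map Non-negative weight matrix (odd dimensions center the
#'   source on the axis).
#' @param spacing Lateral offset between adjacent source samples,
#'   micrometers.
#' @param lam Wavelength; defaults to the scene's first wavelength.
#' @return List with intensity image \code{I}, reference \code{I0}, and
#'   absorbance image \code{A}.
#' @export
extended_source_image <- function(scene, det = NULL, source_map = matrix(1, 1, 1),
                                  spacing = 1, lam = NULL) {
  stopifnot(inherits(scene, "simulation_config"))
  det <- det %||% scene$det
  lam <- lam %||% scene$wavelengths[1]
  source_map <- as.matrix(source_map)
  if (any(source_map < 0) || sum(source_map) <= 0) {
    stop("source_map weights must be >= 0 with positive sum")
  }
  nr <- nrow(source_map); nc <- ncol(source_map)
  wsum <- sum(source_map)
  acc_I <- NULL; acc_I0 <- NULL
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      w <- source_map[i, j]
      if (w <= 0) next
      off <- c((j - (nc + 1) / 2) * spacing, (i - (nr + 1) / 2) * spacing, 0)
      I <- simulate_intensity(lam, scene$na_cond, scene$E0, scene$spheres, det,
                              scene$mc_samples, scene$seed, scene$order,
                              p_f_offset = off)
      I0 <- simulate_intensity(lam, scene$na_cond, scene$E0, scene$spheres, det,
                               scene$mc_samples, scene$seed, scene$order,
                               p_f_offset = off, with_spheres = FALSE)
      if (is.null(acc_I)) {
        acc_I <- I; acc_I0 <- I0
        acc_I$values <- w * I$values
        acc_I0$values <- w * I0$values
      } else {
        acc_I$values <- acc_I$values + w * I$values
        acc_I0$values <- acc_I0$values + w * I0$values
      }
    }
  }
  acc_I$values <- acc_I$values / wsum
  acc_I0$values <- acc_I0$values / wsum
  list(I = acc_I, I0 = acc_I0, A = absorbance_image(acc_I, acc_I0))
}
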