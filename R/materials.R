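## Complex refractive-index spectra: table loading, Lorentz-oscillator
## synthesis, and the Kramers-Kronig route from absorbance measurements.
##
## The canonical abscissa unit is wavelength in micrometers; wavenumber
## (cm^-1) input is converted at the I/O boundary via lambda = 1e4 / nu.

#' Construct a material spectrum
#'
#' A complex refractive index \eqn{n(\lambda) = \eta(\lambda) +
#' i\kappa(\lambda)} sampled on a strictly increasing wavelength grid, with
#' linear interpolation between samples and clamping outside the range.
#'
#' @param wavelengths Wavelength grid, micrometers, strictly increasing, > 0.
#' @param eta Real refractive index samples (> 0).
#' @param kappa Extinction coefficient samples (>= 0).
#' @param n0 Baseline refractive index (default 1.4, typical of polymers).
#' @return Object of class \code{material_spectrum}.
#' @export
material_spectrum <- function(wavelengths, eta, kappa, n0 = 1.4) {
  wavelengths <- as.numeric(wavelengths)
  eta <- as.numeric(eta)
  kappa <- as.numeric(kappa)
  if (length(wavelengths) < 1L) stop("empty wavelength grid")
  if (any(!is.finite(wavelengths)) || any(wavelengths <= 0)) {
    stop("wavelengths must be finite and > 0")
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  if (length(eta) != length(wavelengths) || length(kappa) != length(wavelengths)) {
    stop("eta and kappa must match the wavelength grid length")
  }
  if (any(!is.finite(eta)) || any(eta <= 0)) stop("eta must be finite and > 0")
  if (any(!is.finite(kappa)) || any(kappa < 0)) stop("kappa must be finite and >= 0")
  structure(list(wavelengths = wavelengths, eta = eta, kappa = kappa,
                 n0 = as.numeric(n0)),
            class = "material_spectrum")
}

#' @export
print.material_spectrum <- function(x, ...) {
  cat(sprintf("<material_spectrum> %d samples, lambda %.4g..%.4g um, n0 = %.3g\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths), x$n0))
  cat(sprintf("  eta in [%.4g, %.4g], kappa in [%.4g, %.4g]\n",
              min(x$eta), max(x$eta), min(x$kappa), max(x$kappa)))
  invisible(x)
}

#' Query a material at given wavelengths
#'
#' Linear interpolation on the stored grid; queries outside the grid clamp
#' to the nearest endpoint (no extrapolation).
#'
#' @param material A \code{material_spectrum}.
#' @param lam Wavelengths (micrometers).
#' @return Complex vector \eqn{\eta + i\kappa}.
#' @export
material_at <- function(material, lam) {
  stopifnot(inherits(material, "material_spectrum"))
  if (length(material$wavelengths) == 1L) {
    return(complex(real = rep(material$eta, length(lam)),
                   imaginary = rep(material$kappa, length(lam))))
  }
  e <- stats::approx(material$wavelengths, material$eta, xout = lam, rule = 2)$y
  k <- stats::approx(material$wavelengths, material$kappa, xout = lam, rule = 2)$y
  complex(real = e, imaginary = k)
}

#' Load a refractive-index table from delimited text
#'
#' Three columns (abscissa, eta, kappa), comma- or whitespace-delimited,
#' with optional \code{#} comment lines. Wavenumber abscissae are converted
#' to micrometers (\eqn{\lambda = 10^4/\nu}) and the table re-sorted
#' ascending in wavelength.
#'
#' @param path File path.
#' @param units \code{"micron"} or \code{"inverse_cm"}.
#' @param n0 Baseline refractive index stored with the spectrum.
#' @return A \code{material_spectrum}.
#' @export
load_material_table <- function(path, units = c("micron", "inverse_cm"), n0 = 1.4) {
  units <- match.arg(units)
  rows <- parse_delimited(path, n_cols = 3L)
  ab <- rows[, 1]
  if (any(ab <= 0)) stop("non-positive abscissa in material table: ", path)
  if (any(rows[, 3] < 0)) stop("negative kappa in material table: ", path)
  lam <- if (units == "inverse_cm") 1e4 / ab else ab
  o <- order(lam)
  material_spectrum(lam[o], rows[o, 2], rows[o, 3], n0 = n0)
}

## Shared delimited-text reader: '#' comments, comma or whitespace
## separators, fixed column count, errors name the offending line.
parse_delimited <- function(path, n_cols) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) < 1L) stop("no data rows in ", path)
  vals <- lapply(keep, function(i) {
    toks <- strsplit(trimws(lines[i]), "[,\\s]+", perl = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(toks))
    if (length(v) != n_cols || any(is.na(v))) {
      stop(sprintf("parse error in %s at line %d: '%s'", path, i, lines[i]))
    }
    v
  })
  m <- do.call(rbind, vals)
  if (nrow(m) < 2L) stop("need at least 2 data rows in ", path)
  m
}

#' Derive a complex refractive index from an absorbance spectrum
#'
#' The extinction coefficient follows directly from per-thickness absorbance,
#' \eqn{\kappa(\lambda) = A(\lambda)\lambda/(4\pi)} (taken positive for
#' positive absorbance), and the dispersion \eqn{\eta(\lambda)} is recovered
#' through the Kramers-Kronig relation: the imaginary susceptibility
#' \eqn{\chi'' = 2 n_0 \kappa} is extended as an odd function of frequency
#' and its Hilbert-transform partner \eqn{\chi'} gives
#' \eqn{\eta = n_0 + \chi'/(2 n_0)}. The transform is evaluated on a uniform
#' wavenumber grid by zero-padded FFT (pad factor >= 4 suppresses
#' wrap-around).
#'
#' @param wavelengths Wavelength grid (micrometers); resampled internally to
#'   a uniform frequency grid if needed.
#' @param absorbance Absorbance per micrometer thickness, >= 0, length >= 16.
#' @param n0 Baseline refractive index (default 1.4).
#' @param pad_factor Zero-padding factor for the FFT Hilbert transform.
#' @return A \code{material_spectrum} on the input wavelength grid.
#' @export
kramers_kronig <- function(wavelengths, absorbance, n0 = 1.4, pad_factor = 4) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.numeric(absorbance)
  if (length(wavelengths) < 16L) stop("need at least 16 samples")
  if (length(absorbance) != length(wavelengths)) stop("length mismatch")
  if (any(!is.finite(wavelengths)) || any(!is.finite(absorbance))) {
    stop("non-finite input")
  }
  if (any(wavelengths <= 0)) stop("wavelengths must be > 0")
  if (any(absorbance < 0)) stop("absorbance must be >= 0")
  if (pad_factor < 4) pad_factor <- 4
  o <- order(wavelengths)
  lam <- wavelengths[o]
  A <- absorbance[o]

  ## uniform frequency grid (wavenumber nu = 1/lambda, um^-1)
  nu_in <- rev(1 / lam)
  chi2_in <- rev(2 * n0 * A * lam / (4 * pi))   # chi'' = 2 n0 kappa
  N <- max(256L, 2L * length(lam))
  nu <- seq(min(nu_in), max(nu_in), length.out = N)
  chi2 <- stats::approx(nu_in, chi2_in, xout = nu)$y
  dnu <- nu[2] - nu[1]

  chi1 <- hilbert_partner_odd(nu, chi2, dnu, pad_factor)

  ## back to the input wavelength grid
  chi1_lam <- stats::approx(nu, chi1, xout = 1 / lam, rule = 2)$y
  eta <- n0 + chi1_lam / (2 * n0)
  kappa <- A * lam / (4 * pi)
  out <- material_spectrum(lam, eta, kappa, n0 = n0)
  out
}

## chi'(nu) = (1/pi) PV int chi''(nu')/(nu' - nu) dnu' with chi'' extended
## oddly about nu = 0, computed as a discrete convolution via zero-padded
## FFT. `nu` is the uniform positive-frequency grid carrying chi''.
hilbert_partner_odd <- function(nu, chi2, dnu, pad_factor) {
  ## embed on a symmetric grid [-L, L] covering pad_factor * max(nu)
  K <- as.integer(ceiling(pad_factor * max(nu) / dnu))
  Nfull <- 2L * K + 1L                      # grid -K..K times dnu
  full <- numeric(Nfull)
  idx <- as.integer(round(nu / dnu))        # may be non-integer offsets
  frac_ok <- max(abs(nu / dnu - idx)) < 1e-6
  if (!frac_ok) {
    ## re-interpolate onto the integer lattice
    lattice <- (1:K) * dnu
    chi_l <- stats::approx(nu, chi2, xout = lattice, rule = 1)$y
    chi_l[is.na(chi_l)] <- 0
    full[K + 1L + (1:K)] <- chi_l
    full[K + 1L - (1:K)] <- -chi_l
  } else {
    full[K + 1L + idx] <- chi2
    full[K + 1L - idx] <- -chi2
  }
  ## convolution with the PV kernel 1/(pi u) sampled at the lattice,
  ## regularized at u = 0 (kernel odd, so the singular node contributes 0)
  M <- stats::nextn(2L * Nfull, 2)
  u <- c(0:(M %/% 2), -(M - M %/% 2 - 1L):-1L) * dnu
  kern <- ifelse(u == 0, 0, 1 / (pi * u)) * dnu
  f <- numeric(M)
  f[seq_len(Nfull)] <- full
  conv <- Re(stats::fft(stats::fft(f) * stats::fft(kern), inverse = TRUE)) / M
  ## chi'(x) = sum_s chi''(s) k(s - x): correlation, i.e. conv with k(-u);
  ## kernel is odd so negate the convolution result
  chi1_full <- -conv[seq_len(Nfull)]
  if (!frac_ok) {
    lattice <- (1:K) * dnu
    stats::approx(lattice, chi1_full[K + 1L + (1:K)], xout = nu, rule = 2)$y
  } else {
    chi1_full[K + 1L + idx]
  }
}

#' Synthetic Lorentz-oscillator material
#'
#' Builds a material whose extinction is a sum of Lorentz oscillators (in
#' frequency) and whose dispersion is the matched analytic partner, so the
#' pair satisfies the Kramers-Kronig relations exactly. For each peak,
#' \deqn{\chi(\nu) = F / (\nu_0^2 - \nu^2 - i\gamma\nu)}
#' with \eqn{F} set so the peak extinction equals \code{amplitudes}.
#'
#' @param center_wavelengths Peak centers, micrometers.
#' @param amplitudes Peak extinction values (kappa at center).
#' @param widths Full widths of the peaks in micrometers (at the center).
#' @param n0 Baseline refractive index.
#' @param grid Wavelength grid (micrometers, strictly increasing).
#' @return A \code{material_spectrum}; deterministic.
#' @export
lorentzian_fixture <- function(center_wavelengths = numeric(0),
                               amplitudes = numeric(0),
                               widths = numeric(0),
                               n0 = 1.4,
                               grid = seq(2, 12, length.out = 512)) {
  np <- length(center_wavelengths)
  stopifnot(length(amplitudes) == np, length(widths) == np)
  if (np > 0 && any(widths <= 0)) stop("widths must be > 0")
  nu <- 1 / grid
  chi <- rep(0 + 0i, length(grid))
  for (p in seq_len(np)) {
    lam0 <- center_wavelengths[p]
    if (lam0 < min(grid) || lam0 > max(grid)) {
      warning(sprintf("peak at %.4g um lies outside the grid [%.4g, %.4g]; added anyway",
                      lam0, min(grid), max(grid)))
    }
    nu0 <- 1 / lam0
    gam <- widths[p] / lam0^2        # width mapped from lambda to nu
    FF <- amplitudes[p] * 2 * n0 * gam * nu0
    chi <- chi + FF / (nu0^2 - nu^2 - 1i * gam * nu)
  }
  eta <- n0 + Re(chi) / (2 * n0)
  kappa <- pmax(0, Im(chi) / (2 * n0))
  material_spectrum(grid, eta, kappa, n0 = n0)
}

#' Per-thickness absorbance implied by a material's extinction
#'
#' \eqn{A(\lambda) = 4\pi\kappa(\lambda)/\lambda}, the inverse of the
#' extinction relation used by \code{\link{kramers_kronig}}.
#'
#' @param material A \code{material_spectrum}.
#' @return Data frame with columns \code{wavelength} and \code{absorbance}.
#' @export
absorbance_spectrum <- function(material) {
  stopifnot(inherits(material, "material_spectrum"))
  data.frame(wavelength = material$wavelengths,
             absorbance = 4 * pi * material$kappa / material$wavelengths)
}
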