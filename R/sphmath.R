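## Special-function kernel: spherical Bessel/Hankel families, Legendre
## recursions, annular-aperture coefficients c_l and the convergence order.
##
## Real-argument j_l/y_l are obtained from the half-integer-order cylinder
## Bessel functions in base R (j_l(x) = sqrt(pi/(2x)) J_{l+1/2}(x)); the
## complex-argument j_l needed for fields inside absorbing spheres is
## computed by Miller's downward recurrence with overflow rescaling.

#' Maximum partial-wave order for a converged Mie series
#'
#' Implements the Bohren--Huffman convergence rule
#' \eqn{N_l = \lceil x + 4 x^{1/3} + 2 \rceil} with size parameter
#' \eqn{x = 2\pi a / \lambda}.
#'
#' @param a Sphere radius (or evaluation radius) in micrometers.
#' @param lam Wavelength in micrometers.
#' @return Integer order \eqn{N_l}.
#' @export
#' @examples
#' max_order(3, 2.5)
max_order <- function(a, lam) {
  stopifnot(all(a > 0), all(lam > 0))
  x <- 2 * pi * a / lam
  as.integer(ceiling(x + 4 * x^(1 / 3) + 2))
}

#' Legendre polynomial sequence P_0..P_lmax
#'
#' Three-term recurrence \eqn{l P_l = (2l-1) x P_{l-1} - (l-1) P_{l-2}},
#' vectorized over the abscissa.
#'
#' @param l_max Highest order (integer, >= 0).
#' @param x Abscissa values in \eqn{[-1, 1]}.
#' @return Numeric matrix of dimension (l_max + 1) x length(x); row l + 1
#'   holds \eqn{P_l(x)}.
#' @export
legendre_sequence <- function(l_max, x) {
  l_max <- as.integer(l_max)
  stopifnot(l_max >= 0)
  if (any(abs(x) > 1 + 1e-12)) stop("legendre_sequence: |x| > 1")
  x <- pmin(1, pmax(-1, x))
  n <- length(x)
  P <- matrix(0, nrow = l_max + 1L, ncol = n)
  P[1L, ] <- 1
  if (l_max >= 1L) P[2L, ] <- x
  if (l_max >= 2L) {
    for (l in 2:l_max) {
      P[l + 1L, ] <- ((2 * l - 1) * x * P[l, ] - (l - 1) * P[l - 1L, ]) / l
    }
  }
  P
}

## Spherical Bessel j_l for real non-negative argument, orders 0..l_max.
## Returns (l_max+1) x length(x) matrix. Underflow for large order / small
## argument is mapped to 0 (the analytic x^l limiting form).
sph_bessel_j_real <- function(l_max, x) {
  stopifnot(all(x >= 0))
  n <- length(x)
  out <- matrix(0, nrow = l_max + 1L, ncol = n)
  pos <- x > 0
  xp <- x[pos]
  if (length(xp)) {
    pref <- sqrt(pi / (2 * xp))
    for (l in 0:l_max) {
      v <- suppressWarnings(besselJ(xp, l + 0.5))
      v[!is.finite(v)] <- 0
      out[l + 1L, pos] <- pref * v
    }
  }
  if (any(!pos)) out[1L, !pos] <- 1  # j_0(0) = 1, j_l(0) = 0 for l > 0
  out
}

## Spherical Bessel y_l for real positive argument (singular at 0), via the
## upward recurrence (stable for y). Overflowed entries are +-Inf.
sph_bessel_y_real <- function(l_max, x) {
  if (any(x <= 0)) stop("y_l requires a strictly positive real argument")
  n <- length(x)
  out <- matrix(0, nrow = l_max + 1L, ncol = n)
  out[1L, ] <- -cos(x) / x
  if (l_max >= 1L) out[2L, ] <- -cos(x) / x^2 - sin(x) / x
  if (l_max >= 2L) {
    for (l in 2:l_max) {
      out[l + 1L, ] <- (2 * l - 1) / x * out[l, ] - out[l - 1L, ]
    }
  }
  out
}

## Complex-argument j_l by Miller's downward recurrence, normalized against
## the closed forms j_0 = sin(z)/z or j_1 (whichever is larger, avoiding
## normalization at a zero). Columns are rescaled mid-recurrence when the
## unnormalized values threaten overflow.
sph_bessel_j_complex <- function(l_max, z) {
  z <- as.complex(z)
  n <- length(z)
  out <- matrix(0 + 0i, nrow = l_max + 1L, ncol = n)
  zero <- abs(z) == 0
  out[1L, zero] <- 1 + 0i
  live <- which(!zero)
  if (!length(live)) return(out)
  zl <- z[live]
  l_start <- l_max + 30L + as.integer(ceiling(max(abs(zl))))
  fp1 <- rep(0 + 0i, length(zl))      # f_{l+1}
  f <- rep(1e-30 + 0i, length(zl))    # f_l (arbitrary seed)
  raw <- matrix(0 + 0i, nrow = l_max + 1L, ncol = length(zl))
  if (l_start <= l_max) raw[l_start + 1L, ] <- f
  for (l in l_start:1) {
    fm1 <- (2 * l + 1) / zl * f - fp1
    fp1 <- f
    f <- fm1
    big <- which(abs(f) > 1e250)
    if (length(big)) {
      s <- 1e-250
      f[big] <- f[big] * s
      fp1[big] <- fp1[big] * s
      raw[, big] <- raw[, big] * s
    }
    if (l - 1L <= l_max) raw[l, ] <- f
  }
  j0 <- sin(zl) / zl
  j1 <- sin(zl) / zl^2 - cos(zl) / zl
  use0 <- abs(j0) >= abs(j1)
  scale <- ifelse(use0, j0 / raw[1L, ],
                  if (l_max >= 1L) j1 / raw[2L, ] else j0 / raw[1L, ])
  if (l_max == 0L && any(!use0)) {
    ## need j1 raw value for normalization even when only l=0 requested
    ## (raw row 2 absent); recompute scale from j0 anyway: safe because
    ## use0 is FALSE only near zeros of j0 where raw[1,] is also small but
    ## proportional -- fall back to j1 via the recurrence pair fp1 (= raw j1)
    scale[!use0] <- (j1 / fp1)[!use0]
  }
  out[, live] <- sweep(raw, 2L, scale, `*`)
  out
}

## Derivatives from the stored family: f'_l = f_{l-1} - ((l+1)/z) f_l for
## l >= 1 and f'_0 = -f_1. `fam` is the (l_max+1) x n value matrix.
bessel_derivative <- function(fam, z) {
  l_max <- nrow(fam) - 1L
  d <- fam * 0
  if (l_max >= 1L) {
    lv <- (1:l_max) + 1
    d[2:(l_max + 1L), ] <- fam[1:l_max, , drop = FALSE] -
      sweep(fam[2:(l_max + 1L), , drop = FALSE], 2L, z, `/`) * lv
    d[1L, ] <- -fam[2L, ]
  }
  zz <- which(abs(z) == 0)
  if (length(zz)) {
    d[, zz] <- 0
    if (l_max >= 1L) d[2L, zz] <- 1 / 3  # j_1'(0)
  }
  d
}

#' Spherical Bessel and Hankel function families
#'
#' Computes \eqn{j_l, y_l, h^{(1)}_l} and their derivatives for
#' \eqn{l = 0, \dots, l_{max}}. For real arguments all six families are
#' returned; for genuinely complex arguments only the \eqn{j_l} family (and
#' its derivative) is defined here, which is all the internal-field series
#' requires. Derivatives use \eqn{f'_l = f_{l-1} - ((l+1)/z) f_l}.
#'
#' @param l_max Highest order.
#' @param z Argument vector; real, or complex (for \eqn{j_l} only).
#' @return List with matrices \code{j}, \code{dj} and, for real arguments,
#'   \code{y}, \code{dy}, \code{h1}, \code{dh1}; each (l_max + 1) x length(z).
#' @export
#' @examples
#' fam <- spherical_bessel_family(2, 1.0)
#' fam$j[1, ]  # sin(1)/1
spherical_bessel_family <- function(l_max, z) {
  l_max <- as.integer(l_max)
  stopifnot(l_max >= 0)
  L <- l_max + 1L  # one extra order so f'_0 = -f_1 is available at l_max = 0
  keep <- seq_len(l_max + 1L)
  is_cplx <- is.complex(z) && any(Im(z) != 0)
  if (is_cplx) {
    j <- sph_bessel_j_complex(L, z)
    return(list(j = j[keep, , drop = FALSE],
                dj = bessel_derivative(j, z)[keep, , drop = FALSE],
                y = NULL, dy = NULL, h1 = NULL, dh1 = NULL))
  }
  x <- Re(z)
  j <- sph_bessel_j_real(L, x)
  if (any(x == 0)) {
    ## y_l and h_l are singular at the origin
    if (all(x == 0)) {
      return(list(j = j[keep, , drop = FALSE],
                  dj = bessel_derivative(j, x)[keep, , drop = FALSE],
                  y = NULL, dy = NULL, h1 = NULL, dh1 = NULL))
    }
    stop("y_l / h_l requested at z = 0 (singular)")
  }
  y <- sph_bessel_y_real(L, x)
  h1 <- j + 1i * y
  list(j = j[keep, , drop = FALSE],
       dj = bessel_derivative(j, x)[keep, , drop = FALSE],
       y = y[keep, , drop = FALSE],
       dy = bessel_derivative(y, x)[keep, , drop = FALSE],
       h1 = h1[keep, , drop = FALSE],
       dh1 = bessel_derivative(h1, x)[keep, , drop = FALSE])
}

#' Annular-aperture Legendre coefficients c_l
#'
#' Closed-form weights for the focused-field series over an annular
#' condenser subtending polar angles \eqn{[\alpha_1, \alpha_2]}:
#' \deqn{c_l = P_{l+1}(\cos\alpha_1) - P_{l+1}(\cos\alpha_2)
#'            - P_{l-1}(\cos\alpha_1) + P_{l-1}(\cos\alpha_2)}
#' with the convention \eqn{P_{-1} \equiv 1}, so that
#' \eqn{c_l = (2l+1)\int_{\alpha_1}^{\alpha_2} P_l(\cos\theta)\sin\theta\,
#' d\theta} and \eqn{c_0 = \cos\alpha_1 - \cos\alpha_2}.
#'
#' @param l_max Highest order.
#' @param alpha1,alpha2 Annulus angles in radians, 0 <= alpha1 < alpha2 <= pi.
#' @return Numeric vector c_0..c_{l_max}.
#' @export
aperture_coeffs <- function(l_max, alpha1, alpha2) {
  if (!(alpha1 >= 0 && alpha1 < alpha2 && alpha2 <= pi)) {
    stop("require 0 <= alpha1 < alpha2 <= pi")
  }
  l_max <- as.integer(l_max)
  x <- cos(c(alpha1, alpha2))
  P <- legendre_sequence(l_max + 1L, x)     # rows P_0 .. P_{l_max+1}
  ## P_{l-1} with P_{-1} := 1
  Pm1 <- rbind(c(1, 1), P[seq_len(l_max), , drop = FALSE])
  Pp1 <- P[2:(l_max + 2L), , drop = FALSE]
  (Pp1[, 1] - Pp1[, 2]) - (Pm1[, 1] - Pm1[, 2])
}
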