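## Independent oracles and frozen reference values for the test suite.

## ---- frozen arbitrary-precision values (computed once with mpmath at
## 40 significant digits; spherical Bessel j_l(z) for complex z) ----------
jl_oracle <- list(
  list(l = 0L, z = 0.3 + 0i, v = 0.98506735553779858 + 0i),
  list(l = 0L, z = 2.0 + 0.5i, v = 0.45700439899001896 - 0.2226771812078996i),
  list(l = 0L, z = 10 + 3i, v = -0.73382887642506923 - 0.62042270041632738i),
  list(l = 0L, z = 25 + 1i, v = -0.0062953240197275658 + 0.046846322066590964i),
  list(l = 0L, z = 0.05 + 0.02i, v = 0.99965000341982897 - 0.00033326333699601279i),
  list(l = 1L, z = 2.0 + 0.5i, v = 0.46543564095115258 + 0.0092178093664655527i),
  list(l = 1L, z = 10 + 3i, v = 0.54060112150863134 - 0.76921615117025212i),
  list(l = 1L, z = 0.05 + 0.02i, v = 0.016664499824430471 + 0.0066619338430819174i),
  list(l = 2L, z = 2.0 + 0.5i, v = 0.20333455624683134 + 0.07141915644838535i),
  list(l = 2L, z = 25 + 1i, v = -0.0010828360772638037 - 0.046777688786202992i),
  list(l = 5L, z = 2.0 + 0.5i, v = 0.0012755268915548847 + 0.0028231928670882461i),
  list(l = 5L, z = 10 + 3i, v = -0.44512177257728978 - 0.48733594008270423i),
  list(l = 5L, z = 30 + 3i, v = -0.21879327702549149 - 0.23253516119683138i),
  list(l = 5L, z = 0.05 + 0.02i, v = -1.4185199655733191e-11 + 4.1190645511072618e-11i),
  list(l = 10L, z = 2.0 + 0.5i, v = -6.8906008848351163e-08 + 6.2359975284277003e-08i),
  list(l = 10L, z = 10 + 3i, v = 0.033220345130205647 + 0.14196395829584416i),
  list(l = 10L, z = 25 + 1i, v = -0.051307824294979913 + 0.024091830572738366i),
  list(l = 10L, z = 0.05 + 0.02i, v = -1.1753105996660471e-23 - 9.1863666063381086e-24i),
  list(l = 20L, z = 2.0 + 0.5i, v = 2.2899357596116503e-20 - 1.384765182057999e-19i),
  list(l = 20L, z = 10 + 3i, v = 2.3137377197668714e-06 - 5.7336955091598326e-06i),
  list(l = 20L, z = 25 + 1i, v = 0.032267652536240996 - 0.029165630788906954i),
  list(l = 20L, z = 0.05 + 0.02i, v = 7.7468089749884035e-52 + 3.1132916300781733e-51i),
  list(l = 30L, z = 2.0 + 0.5i, v = 7.2209988236985358e-34 + 1.2596853170650392e-33i),
  list(l = 30L, z = 10 + 3i, v = -3.8715451881544246e-13 + 9.0924607277699907e-13i),
  list(l = 30L, z = 25 + 1i, v = 0.0016542232963016902 + 0.0014317685688157637i),
  list(l = 30L, z = 30 + 3i, v = 0.023026933750004331 + 0.034030394346702101i)
)

## Mie coefficients for a = 1 um, n = 1.5 + 0.01i, lambda = 2.5 um
## (same 40-digit mpmath pipeline, orders 0..8).
mie_oracle <- list(
  B = c(-0.76738452444831041 + 0.4012868582319759i,
        -0.61443705043019972 - 2.7948859437455684i,
        1.4836274900929441 - 2.1313331748536764i,
        0.28578126292418465 + 0.021830950940170148i,
        -0.0006781186909906103 + 0.021452833498109034i,
        -0.00115200503284845 - 3.1382095539000959e-05i,
        1.1699705196084585e-06 - 4.4742410915824115e-05i,
        1.3025700418266269e-06 + 3.3317013507303148e-08i,
        -7.4135068914418825e-10 + 2.9399980213866312e-08i),
  A = c(0.50633426088237319 + 0.96776532742506454i,
        -3.2053911385367733 + 0.75124208313268683i,
        -6.3582109449959319 - 4.1924550154971207i,
        0.18512724973283413 - 4.4301947892578695i,
        2.9671356436985292 - 0.033307610142592671i,
        0.05031344632581034 + 2.1480520616198668i,
        -1.5768005874397756 + 0.050524282804622976i,
        -0.046168146501070729 - 1.155755909206663i,
        0.84280398082277002 - 0.040041401238591854i),
  a = 1, n = 1.5 + 0.01i, lam = 2.5
)

## ---- closed-form Legendre polynomials (independent of the package's
## recurrence), orders 0..9, for the quadrature cross-check -----------------
legendre_closed <- function(l, x) {
  switch(l + 1L,
    x * 0 + 1,
    x,
    (3 * x^2 - 1) / 2,
    (5 * x^3 - 3 * x) / 2,
    (35 * x^4 - 30 * x^2 + 3) / 8,
    (63 * x^5 - 70 * x^3 + 15 * x) / 8,
    (231 * x^6 - 315 * x^4 + 105 * x^2 - 5) / 16,
    (429 * x^7 - 693 * x^5 + 315 * x^3 - 35 * x) / 16,
    (6435 * x^8 - 12012 * x^6 + 6930 * x^4 - 1260 * x^2 + 35) / 128,
    (12155 * x^9 - 25740 * x^7 + 18018 * x^5 - 4620 * x^3 + 315 * x) / 128,
    stop("closed form only to l = 9"))
}

## ---- focused-field oracle: direct numerical integration of the aperture
## cap (azimuthal integral done analytically via J_0), Simpson rule ---------
focused_field_oracle <- function(cfg, points, n_nodes = 2001L) {
  if (n_nodes %% 2L == 0L) n_nodes <- n_nodes + 1L
  th <- seq(cfg$alpha1, cfg$alpha2, length.out = n_nodes)
  h <- th[2] - th[1]
  w <- c(1, rep(c(4, 2), length.out = n_nodes - 2L), 1)
  w[n_nodes] <- 1
  rel <- sweep(as.matrix(points), 2L, cfg$p_f)
  rho <- sqrt(rel[, 1]^2 + rel[, 2]^2)
  z <- rel[, 3]
  acc <- complex(length(rho))
  for (i in seq_along(th)) {
    acc <- acc + (w[i] * sin(th[i])) *
      besselJ(cfg$k * rho * sin(th[i]), 0) * exp(1i * cfg$k * z * cos(th[i]))
  }
  2 * pi * cfg$E0 * acc * h / 3
}

## ---- Kramers-Kronig oracle: direct principal-value quadrature of the
## one-sided dispersion integral on the sample grid, with the singularity
## subtracted analytically: writing g(s) = 2 s chi2(s) / (s + x),
##   chi'(x) = (1/pi) [ int (g(s) - g(x)) / (s - x) ds
##                      + g(x) log((b - x)/(x - a)) ]
kk_pv_oracle <- function(nu, chi2) {
  dnu <- nu[2] - nu[1]
  a <- min(nu); b <- max(nu)
  vapply(seq_along(nu), function(i) {
    x <- nu[i]
    g <- 2 * nu * chi2 / (nu + x)
    gx <- 2 * x * chi2[i] / (2 * x)
    num <- (g - gx) / (nu - x)
    ## removable singularity: the difference quotient tends to g'(x)
    num[i] <- if (i > 1L && i < length(nu)) {
      (g[i + 1L] - g[i - 1L]) / (2 * dnu)
    } else 0
    log_term <- if (i == 1L || i == length(nu)) 0 else log((b - x) / (x - a))
    (1 / pi) * (sum(num) * dnu + gx * log_term)
  }, numeric(1))
}

## ---- small scene helpers ---------------------------------------------------
surface_points <- function(a, n_pts = 64L, seed = 5L) {
  set.seed(seed)
  th <- acos(stats::runif(n_pts, -1, 1))
  ph <- stats::runif(n_pts, 0, 2 * pi)
  a * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

## Boundary-continuity mismatch for a single plane wave along +z:
## internal branch at r = a versus exact plane wave + scattered series just
## outside the surface.
continuity_mismatch <- function(a, n, lam, n_pts = 64L) {
  co <- scattering_coefficients(a, n, lam)
  sph <- sphere(c(0, 0, 0), a, n)
  pts <- surface_points(a, n_pts)
  Ei <- planewave_sphere_field(sph, co, c(0, 0, 1), c(0, 0, 0), pts)
  po <- pts * (1 + 2e-9)
  Es <- planewave_sphere_field(sph, co, c(0, 0, 1), c(0, 0, 0), po)
  Epw <- exp(1i * 2 * pi / lam * po[, 3])
  max(abs(Ei - (Es + Epw))) / max(abs(Ei))
}
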