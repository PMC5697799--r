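test_that("scattering coefficients match the frozen arbitrary-precision oracle", {
  co <- scattering_coefficients(mie_oracle$a, mie_oracle$n, mie_oracle$lam)
  idx <- seq_along(mie_oracle$B)
  expect_lt(max(abs(co$B[idx] - mie_oracle$B) / abs(mie_oracle$B)), 1e-12)
  expect_lt(max(abs(co$A[idx] - mie_oracle$A) / abs(mie_oracle$A)), 1e-12)
})

test_that("null scatterer: n = 1 gives B = 0 and the incident expansion for A", {
  co <- scattering_coefficients(1, 1 + 0i, 2.5)
  expect_lt(max(abs(co$B)), 1e-12)
  l <- 0:co$l_max
  expect_equal(co$A, (2 * l + 1) * 1i^l, tolerance = 1e-10)
})

test_that("boundary continuity across materials and size parameters", {
  lam <- 2.5
  for (ka in c(1, 5, 15)) {
    for (nn in c(1.5 + 0i, 1.5 + 0.1i, 2.4 + 0i)) {
      a <- ka * lam / (2 * pi)
      expect_lt(continuity_mismatch(a, nn, lam), 1e-6,
                label = sprintf("ka=%g n=%s", ka, format(nn)))
    }
  }
})

test_that("coefficient decay validates the convergence-order rule", {
  lam <- 2.5
  for (ka in c(1, 5, 15)) {
    for (nn in c(1.5 + 0i, 1.5 + 0.1i, 2.4 + 0i)) {
      a <- ka * lam / (2 * pi)
      n12 <- max_order(a, lam)
      co <- scattering_coefficients(a, nn, lam)
      expect_gte(co$l_max, n12)
      expect_lt(abs(co$B[n12 + 1L]) / max(abs(co$B)), 1e-6)
    }
  }
})

test_that("off-focus spheres acquire exactly the plane-wave phase shift", {
  lam <- 2.5; k <- 2 * pi / lam
  n <- 1.4 + 0.02i
  co <- scattering_coefficients(0.8, n, lam)
  dirv <- c(0, 0, 1)
  pts <- surface_points(1.6, 20, seed = 9)
  base <- planewave_sphere_field(sphere(c(0, 0, 0), 0.8, n), co, dirv,
                                 c(0, 0, 0), pts)
  ## parallel offset: field at translated points gains e^{ik delta}
  for (delta in c(0.37, -1.21)) {
    shifted <- planewave_sphere_field(sphere(c(0, 0, delta), 0.8, n), co, dirv,
                                      c(0, 0, 0),
                                      sweep(pts, 2L, c(0, 0, delta), `+`))
    expect_lt(max(abs(shifted - exp(1i * k * delta) * base)), 1e-10)
  }
  ## perpendicular offset: phase factor unchanged
  perp <- planewave_sphere_field(sphere(c(2.4, -0.7, 0), 0.8, n), co, dirv,
                                 c(0, 0, 0),
                                 sweep(pts, 2L, c(2.4, -0.7, 0), `+`))
  expect_lt(max(abs(perp - base)), 1e-10)
})

test_that("sphere at the focal point needs no phase shift; r = 0 is handled", {
  co <- scattering_coefficients(1, 1.5 + 0.01i, 2.5)
  sph <- sphere(c(0, 0, 0), 1, 1.5 + 0.01i)
  v_center <- planewave_sphere_field(sph, co, c(0, 0, 1), c(0, 0, 0),
                                     c(0, 0, 0))
  ## only l = 0 contributes at the center (j_l(0) = delta_l0), and the
  ## focal sphere carries no phase shift
  expect_equal(v_center, co$A[1], tolerance = 1e-12)
})

test_that("scatter domain reproduces the direct series and is continuous at d = a", {
  co <- scattering_coefficients(1, 1.5 + 0.01i, 2.5)
  sph <- sphere(c(0, 0, 0), 1, 1.5 + 0.01i)
  dom <- scatter_domain(sph, co, fov = 10, R = 256, R_theta = 1000)
  ## node equality (external and internal)
  d_nodes <- c(dom$d_ext[c(1, 57, 256)], dom$d_int[2])
  ct_nodes <- dom$costh[c(1, 250, 1000)]
  for (d in d_nodes) for (ct in ct_nodes) {
    pt <- matrix(c(d * sqrt(1 - ct^2), 0, d * ct), ncol = 3)
    expect_equal(sample_scatter_domain(dom, d, ct),
                 planewave_sphere_field(sph, co, c(0, 0, 1), c(0, 0, 0), pt),
                 tolerance = 1e-9)
  }
  ## internal/external continuity at the surface
  ct <- seq(-1, 1, length.out = 33)
  vi <- sample_scatter_domain(dom, rep(1 - 1e-12, 33), ct)
  pw <- exp(1i * 2 * pi / 2.5 * 1 * ct)  # incident plane wave at the surface
  ve <- sample_scatter_domain(dom, rep(1 + 1e-9, 33), ct) + pw
  expect_lt(max(abs(vi - ve)) / max(abs(vi)), 1e-5)
  ## random probes within 1e-3 relative of the direct series
  set.seed(4)
  d <- stats::runif(100, 0, 5); ct <- stats::runif(100, -1, 1)
  direct <- vapply(seq_along(d), function(i) {
    pt <- matrix(c(d[i] * sqrt(1 - ct[i]^2), 0, d[i] * ct[i]), ncol = 3)
    planewave_sphere_field(sph, co, c(0, 0, 1), c(0, 0, 0), pt)
  }, complex(1))
  got <- sample_scatter_domain(dom, d, ct)
  expect_lt(max(Mod(got - direct)) / max(Mod(direct)), 1e-3)
  ## clamp warning beyond fov/2
  expect_warning(sample_scatter_domain(dom, 9, 0.2), "clamped")
})

test_that("sub-Nyquist angular sampling degrades interpolation accuracy", {
  co <- scattering_coefficients(2, 1.5 + 0.01i, 2.5)
  sph <- sphere(c(0, 0, 0), 2, 1.5 + 0.01i)
  err_for <- function(R_theta) {
    dom <- suppressWarnings(scatter_domain(sph, co, fov = 12, R = 128,
                                           R_theta = R_theta))
    set.seed(8)
    d <- stats::runif(60, 3.5, 5.8); ct <- stats::runif(60, -1, 1)
    direct <- vapply(seq_along(d), function(i) {
      pt <- matrix(c(d[i] * sqrt(1 - ct[i]^2), 0, d[i] * ct[i]), ncol = 3)
      planewave_sphere_field(sph, co, c(0, 0, 1), c(0, 0, 0), pt)
    }, complex(1))
    max(Mod(sample_scatter_domain(dom, d, ct) - direct)) / max(Mod(direct))
  }
  expect_lt(err_for(2L * co$l_max), err_for(co$l_max))
})

test_that("aperture sampling: cap bounds, degenerate cap, uniform-z mean, determinism", {
  s <- aperture_samples(asin(0.34), asin(0.62), 5000, seed = 2)
  ang <- acos(s$directions[, 3])
  expect_true(all(ang >= asin(0.34) - 1e-12 & ang <= asin(0.62) + 1e-12))
  expect_equal(sqrt(rowSums(s$directions^2)), rep(1, 5000), tolerance = 1e-12)
  ## degenerate cap: all directions collapse to +z
  s0 <- aperture_samples(0, 1e-6, 50, seed = 1)
  expect_lt(max(abs(s0$directions[, 3] - 1)), 1e-9)
  ## mean z for a full cap is (1 + cos(alpha2)) / 2 within 3 standard errors
  a2 <- asin(0.62)
  su <- aperture_samples(0, a2, 1e5, seed = 3, stratify = FALSE)
  z <- su$directions[, 3]
  se <- stats::sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z) - (1 + cos(a2)) / 2), 3 * se)
  ## bit-for-bit determinism per seed
  expect_identical(aperture_samples(0, a2, 777, seed = 42)$directions,
                   aperture_samples(0, a2, 777, seed = 42)$directions)
  expect_false(identical(aperture_samples(0, a2, 777, seed = 43)$directions,
                         aperture_samples(0, a2, 777, seed = 42)$directions))
})

test_that("MC aperture integration converges to the closed-form focused field (n = 1)", {
  ## with n = 1 the internal MC field is an MC estimate of the focused field,
  ## making the closed-form series an independent check of the Eq-13 weight
  cfg <- optical_config(2.5, na = c(0, 0.8))
  sph1 <- sphere(c(0, 0, 0), 1.5, 1 + 0i)
  co1 <- scattering_coefficients(1.5, 1 + 0i, 2.5)
  smp <- aperture_samples(cfg$alpha1, cfg$alpha2, 10000, seed = 5)
  pts <- rbind(c(0, 0, 0), c(0.4, 0, 0.3), c(0, 1.0, -0.8))
  got <- mc_sphere_field(sph1, co1, smp, cfg, pts)
  want <- focused_field(cfg, pts)
  expect_lt(max(Mod(got - want) / Mod(want)), 0.005)
})

test_that("MC estimator is unbiased and rotationally symmetric at focus", {
  cfg <- optical_config(2.5, na = c(0, 0.8))
  a <- 1.5; n <- 1.5 + 0.01i
  sph <- sphere(c(0, 0, 0), a, n)
  co <- scattering_coefficients(a, n, 2.5)
  probe <- matrix(c(0, 0, a), ncol = 3)
  ref <- mc_sphere_field(sph, co, aperture_samples(cfg$alpha1, cfg$alpha2, 1e4, 1),
                         cfg, probe)
  vals <- vapply(1:200, function(s) {
    mc_sphere_field(sph, co,
                    aperture_samples(cfg$alpha1, cfg$alpha2, 25, s, stratify = FALSE),
                    cfg, probe)
  }, complex(1))
  se <- stats::sd(Re(vals)) / sqrt(200) + stats::sd(Im(vals)) / sqrt(200)
  expect_lt(Mod(mean(vals) - ref), 3 * se + 0.005 * Mod(ref))
  ## centered sphere: the aperture-integrated field is rotationally
  ## symmetric, so ring-to-ring variation must sit within MC noise (range
  ## of 8 draws vs the replicate standard deviation at one ring point)
  ph <- seq(0, 2 * pi, length.out = 9)[-9]
  ring_pts <- a * cbind(0.8 * cos(ph), 0.8 * sin(ph), rep(0.6, 8))
  smp <- aperture_samples(cfg$alpha1, cfg$alpha2, 400, seed = 6)
  ring <- Mod(mc_sphere_field(sph, co, smp, cfg, ring_pts))
  reps <- vapply(1:20, function(s) {
    smp_r <- aperture_samples(cfg$alpha1, cfg$alpha2, 400, seed = 100 + s)
    Mod(mc_sphere_field(sph, co, smp_r, cfg, ring_pts[1, , drop = FALSE]))
  }, numeric(1))
  expect_lt(max(ring) - min(ring), 6 * stats::sd(reps))
})

test_that("total field: no spheres, null scatterer, and overlap handling", {
  cfg <- optical_config(2.5, na = c(0.34, 0.62))
  pts <- rbind(c(0, 0, 0), c(1, 0.5, -2), c(-3, 1, 1))
  expect_equal(total_field(cfg, list(), NULL, pts), focused_field(cfg, pts))
  ## null scatterer leaves the focused field unchanged to MC tolerance
  smp <- aperture_samples(cfg$alpha1, cfg$alpha2, 2000, seed = 7)
  sph1 <- sphere(c(0.3, 0, 0.2), 1, 1 + 0i)
  got <- total_field(cfg, list(sph1), smp, pts)
  want <- focused_field(cfg, pts)
  expect_lt(max(Mod(got - want) / Mod(want)), 1e-3)
  ## overlapping spheres warn at scene level and error if a point is shared
  s_a <- sphere(c(0, 0, 0), 1, 1.5 + 0i)
  s_b <- sphere(c(0.5, 0, 0), 1, 1.5 + 0i)
  expect_warning(miescope:::check_sphere_overlap(list(s_a, s_b)), "overlap")
  expect_error(suppressWarnings(total_field(cfg, list(s_a, s_b), smp,
                                            rbind(c(0.25, 0, 0)))),
               "inside two")
})

test_that("surface fields: icosphere counts, plane-wave ring symmetry, off-focus asymmetry", {
  expect_equal(nrow(icosphere(0)$vertices), 12L)
  expect_equal(nrow(icosphere(1)$vertices), 42L)
  expect_equal(nrow(icosphere(2)$vertices), 162L)
  expect_equal(sqrt(rowSums(icosphere(2)$vertices^2)), rep(1, 162),
               tolerance = 1e-12)
  ## centered sphere under one plane wave: |field| constant on cos-theta rings
  co <- scattering_coefficients(1, 1.5 + 0.01i, 2.5)
  sph <- sphere(c(0, 0, 0), 1, 1.5 + 0.01i)
  ph <- seq(0, 2 * pi, length.out = 13)[-13]
  for (ct in c(-0.4, 0.6)) {
    st <- sqrt(1 - ct^2)
    ring <- planewave_sphere_field(sph, co, c(0, 0, 1), c(0, 0, 0),
                                   cbind(st * cos(ph), st * sin(ph), ct))
    expect_lt(max(Mod(ring - ring[1])), 1e-10)
  }
  ## off-focus sphere in a focused beam: phi-dependence appears
  cfg <- optical_config(2.5, na = c(0, 0.62))
  smp <- aperture_samples(cfg$alpha1, cfg$alpha2, 800, seed = 3)
  off <- sphere(c(2.5, 0, 0), 1, 1.5 + 0.01i)
  co_off <- scattering_coefficients(1, 1.5 + 0.01i, 2.5)
  ring_pts <- sweep(cbind(sqrt(1 - 0.25) * cos(ph), sqrt(1 - 0.25) * sin(ph),
                          rep(0.5, 12)), 2L, off$center, `+`)
  vals <- Mod(mc_sphere_field(off, co_off, smp, cfg, ring_pts))
  expect_gt((max(vals) - min(vals)) / mean(vals), 0.05)
  ## surface_field mesh: values at vertices match total_field
  mesh <- surface_field(sph, cfg, list(sph), smp, n_vertices = 42L)
  expect_equal(mesh$values,
               total_field(cfg, list(sph), smp, mesh$vertices),
               tolerance = 1e-12)
})

test_that("three-sphere row: center sphere dominates the surface field", {
  sim <- demo_scene_three_spheres(mc_samples = 120L, seed = 2L)
  lam <- sim$wavelengths[1]
  cfg <- optical_config(lam, na = sim$na_cond)
  smp <- aperture_samples(cfg$alpha1, cfg$alpha2, sim$mc_samples, sim$seed)
  mags <- vapply(sim$spheres, function(s) {
    max(surface_field(s, cfg, sim$spheres, smp, n_vertices = 42L)$magnitude)
  }, numeric(1))
  expect_gt(mags[2], mags[1])
  expect_gt(mags[2], mags[3])
})
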