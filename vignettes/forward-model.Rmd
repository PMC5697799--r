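---
title: "The miescope forward model: assumptions, parameters, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The miescope forward model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miescope)
```

## Scope and assumptions

`miescope` simulates the scalar electromagnetic field in a microscope-like
optical train — annular condenser, spherical scatterers anywhere in the
focal volume, band-limiting objective, detector — for broadband
(wavelength-scanned) illumination. The core modeling assumptions are:

- **Scalar fields.** Polarization is ignored; each plane-wave component is
  a complex scalar. This is the standard first approximation at the
  moderate numerical apertures (NA ≤ ~0.6–0.8) of mid-infrared
  microspectroscopy; vector (Richards–Wolf) corrections grow with NA and
  are out of scope.
- **Single scattering across spheres.** Each sphere scatters the focused
  incident field only; spheres do not re-scatter each other's fields.
  Inside a sphere the field is that sphere's internal series alone. This is
  a Born-type superposition: accurate for well-separated or weakly
  contrasting particles, increasingly wrong for touching high-contrast
  ones. A multi-sphere T-matrix treatment is deliberately out of scope.
- **Homogeneous isotropic spheres** with wavelength-dependent complex
  refractive index n(λ) = η + iκ, κ ≥ 0 (time convention e^{−iωt}, so
  h⁽¹⁾_l is the outgoing wave and absorption means Im n ≥ 0).
- **Unit magnification, aberration-free imaging.** The image plane is the
  objective focal plane through the condenser focus; the objective acts
  purely as an annular spatial-frequency mask with cutoffs NA_in/λ and
  NA_o/λ.

## The field model

The total field at a point is the focused incident field plus every
sphere's scattered field (outside all spheres), or the containing sphere's
internal field (inside one). The incident field of an annulus subtending
polar angles [α₁, α₂] about the +z optical axis has the closed form

$$E_f(p) = 2\pi E_0 \sum_{l=0}^{L} i^l j_l(kr)\, P_l(\cos\theta)\, c_l,
\qquad c_l = P_{l+1}(x_1) - P_{l+1}(x_2) - P_{l-1}(x_1) + P_{l-1}(x_2),$$

with $x_i = \cos\alpha_i$ and the convention $P_{-1} \equiv 1$. With that
convention $c_l$ equals $(2l+1)$ times the aperture integral
$\int_{\alpha_1}^{\alpha_2} P_l(\cos\theta_k)\sin\theta_k\,d\theta_k$, which
is what the derivation from the plane-wave superposition requires — the
package verifies this against adaptive quadrature of closed-form Legendre
polynomials, and verifies the whole series against brute-force numerical
integration of plane waves over the aperture cap (0.5% RMS criterion; the
measured agreement is ~1e-13, i.e. the two routes are analytically
identical up to quadrature error).

For a single plane wave along $\hat{k}$, a sphere at $p_s$ contributes

$$E_s = e^{ik\hat{k}\cdot c}\sum_l B_l\, h^{(1)}_l(kr) P_l(\cos\theta),
\qquad
E_i = e^{ik\hat{k}\cdot c}\sum_l A_l\, j_l(knr) P_l(\cos\theta),$$

where $c = p_s - p_f$ produces the phase delay of an off-focus particle
(a pure translation property, tested to 1e-10). The coefficients follow
from continuity at $r = a$; the printed source formula contains a
dimensionally impossible $j'_l(k)$ which is implemented as $j'_l(ka)$ —
with that reading, value continuity holds algebraically order by order,
and numerically to better than 5e-8 across ka ∈ {1, 5, 15},
n ∈ {1.5, 1.5+0.1i, 2.4}.

### Series order

The Mie series is truncated at the Bohren–Huffman bound
$N_l = \lceil x + 4x^{1/3} + 2\rceil$, $x = 2\pi a/\lambda$
(`max_order`). Two refinements, decided after measurement:

- The truncation error of the *total* field at the surface is governed by
  the per-order surface terms $|B_l h^{(1)}_l(ka)|$ and
  $|A_l j_l(kna)|$, not by the raw coefficient magnitudes: $|A_l|$ alone
  decays only like $|n|^{-l}$ and never decays at $n = 1$. The
  coefficient constructor therefore extends the order until both surface
  terms have fallen below 1e-6 of their peak (for $B_l$ this coincides
  with plain coefficient decay). In practice this adds ~40% over the
  bound and buys the boundary-continuity criterion two orders of
  magnitude of headroom.
- Sphere-free point-spread-function renders default to order 100 (or the
  radius-dependent bound when that is larger), so that wide-field slices
  converge out to their corners. An explicitly set order that is too small
  for the evaluation radius triggers a truncation warning rather than an
  error.

### Special functions

Real-argument spherical Bessel functions come from base R's half-integer
cylinder Bessel routines; $y_l$ uses the (upward-stable) recurrence.
Complex-argument $j_l$ — needed for internal fields of absorbing spheres —
is computed by Miller's downward recurrence with overflow rescaling and
normalization against $j_0$ or $j_1$ (whichever is larger, avoiding zeros),
validated to 1e-8 relative against frozen 40-digit arbitrary-precision
values. Derivatives use $f'_l = f_{l-1} - ((l+1)/z) f_l$ exactly.

## Monte-Carlo aperture integration

The focused-beam response of a sphere is the aperture integral of the
plane-wave solution. It is estimated from $M$ directions drawn uniformly on
the spherical annulus via the cylinder-projection (Archimedes) map, with
jittered stratified sampling in $(\phi, z)$ over
$[0, 2\pi]\times[\cos\alpha_2, \cos\alpha_1]$ — about $\sqrt{M}\times\sqrt{M}$
strata, one jittered sample each — and the estimate

$$E \approx \frac{2\pi E_0[(1-\cos\alpha_2)-(1-\cos\alpha_1)]}{M}
\sum_j E(p, \hat{k}_j).$$

The weight is the annulus solid angle, which makes the $n = 1$
null-scatterer internal estimate exactly an MC estimate of $E_f$ — the
package uses this as an end-to-end check of the normalization (no extra
constant is needed to reconcile the closed-form and MC routes).

Two deliberate choices:

- **One shared direction set per wavelength** for all spheres: physically
  they see the same incident decomposition, and sharing preserves
  inter-sphere coherence in the superposed field.
- **Error decay.** For smooth aperture integrands, jittered stratified
  sampling in 2D converges at ~$M^{-1}$, not the textbook $M^{-1/2}$ — the
  measured replicate-spread slope over $M \in \{25, 100, 400, 1600\}$ is
  ≈ −1.0, which matches the $1/N$ decay the method's original description
  reports for its own convergence study. Plain uniform sampling
  (`aperture_samples(stratify = FALSE)`) recovers the textbook −0.5 slope;
  both are asserted in the acceptance suite. At $M = 400$ the estimate at
  a near-focus surface point is within 2% of an $M = 10^4$ reference
  (typically < 1%).

Sampling is deterministic per seed (bit-for-bit), and all package
randomness is isolated from the caller's RNG state.

Points exactly on a sphere surface (within $10^{-9}a$) evaluate the
internal branch; internal and external series agree there by construction.
A sphere whose refractive index equals 1 at the current wavelength is
optically absent and is dropped from the scene, making the null-scatterer
identity exact rather than noisy.

### Scatter-domain tables

Because the single-plane-wave solution depends only on the distance $d$
from the sphere center and $\cos\theta$ to the propagation direction, it
can be tabulated once per sphere as a 2D table (external $d \ge a$,
internal $d \le a$) and bilinearly interpolated per MC sample, with the
direction-dependent phase applied at lookup (the table stores the
un-shifted field, since the offset $c$ is fixed while $\hat{k}_j$ varies).
The Nyquist rule $R_\theta \ge 2N_l$ follows from the $l$ oscillations of
the highest Legendre order; the default $R_\theta = 1000$ matches the
original tool, and a sub-Nyquist table is demonstrably (and testably) less
accurate. Direct series evaluation is the default path; the table is an
opt-in accelerator with a measured ~1e-3 interpolation error bound at
$R = 256$.

A similar cache exists for the incident field: by rotational symmetry about
the optical axis, one quarter cross-section in cylindrical $(u, v)$
determines $E_f$ everywhere, with the $u < 0$ half obtained by conjugating
the phase relative to $E_0$ (the series terms $i^l j_l P_l c_l$ flip to
their conjugates under $z \to -z$).

## Imaging

`objective_bandpass` applies the annular transfer function in the discrete
frequency domain (step $1/S$ for field-of-view $S$), with the radial
frequency computed from signed FFT frequencies and a boundary-inclusive
pass band (frequencies equal to a cutoff pass, matching the strict
inequalities of the blocking condition). The filter is a projection
(idempotent to 1e-12) and passes/blocks probe sinusoids correctly to within
one frequency bin. Detector resampling is a block mean over each pixel
footprint — flux-preserving, and exactly invariant in mean intensity under
the choice of detector resolution.

Absorbance is $-\log_{10}(I/I_0)$ with $I_0$ from the identical
configuration without spheres. Pixels whose reference intensity falls below
$10^{-12}\max I_0$ are masked invalid (NA plus an explicit logical mask)
rather than given sentinel values. Note that a sphere with purely real
index still produces absorbance structure — scattering redirects light out
of the collection cone — and coherent fringes make small negative
absorbance values physical.

Extended sources are incoherent weighted sums of displaced point sources:
each source-map sample laterally displaces the condenser focus in object
space (map spacing is user-given; no source-to-object magnification model
is imposed), the coherent pipeline runs per sample, and intensities are
weight-averaged. The reference $I_0$ is computed with the *matching*
extended source — the alternative (per-point $I_0$) is not what a real
instrument ratio does.

Per-pixel spectra re-run the full pipeline per wavelength, re-deriving the
series order from the convergence bound each time; material tables clamp
to their nearest endpoint outside their range.

## Materials and Kramers–Kronig

The canonical abscissa is wavelength in micrometers; wavenumber (cm⁻¹)
input is converted only at I/O boundaries (λ = 10⁴/ν). Tables are linearly
interpolated and clamp outside their range (extrapolating η or κ can
produce unphysical values).

The extinction implied by per-thickness absorbance is
$\kappa = +A\lambda/(4\pi)$. The source text prints this relation with a
minus sign, which would make extinction negative for positive absorbance,
contradicting its own definition of κ as quantifying absorption; the
package uses the positive convention.

The dispersion is recovered through the Kramers–Kronig relation applied in
the *frequency* domain (where the susceptibility is analytic): χ″ = 2n₀κ is
resampled onto a uniform wavenumber grid, extended as an odd function about
ν = 0, and convolved with the principal-value kernel by zero-padded FFT
(pad factor ≥ 4 suppresses circular wrap-around). Then
η = n₀ + χ′/(2n₀), with baseline n₀ = 1.4 by default (typical of polymers).
The implementation is cross-checked against an independent direct
principal-value quadrature with analytic singularity subtraction, and
round-trips a Lorentz-oscillator fixture to ~0.08% in η mid-grid (the 1%
criterion); accuracy degrades within ~1 µm of the grid edges, where the
odd extension truncates the oscillator tails — the documented edge window.

The synthetic material generator builds χ(ν) = F/(ν₀² − ν² − iγν) per peak
— an exact Hilbert-transform pair — with F chosen so the peak extinction
equals the requested amplitude, width mapped from wavelength to frequency
at the peak, and a warning (not an error) for peaks outside the grid.

## Synthetic scenes: what a green test establishes

The package generates all of its own test inputs: Lorentz-oscillator
materials, random sphere layouts, random field slices. These emulate the
*mathematical* structure of real measurements (dispersion consistent with
causality, focused illumination, band-limited detection) but not their
noise, instrument line shapes, detector nonlinearity, substrate
reflections, or particle non-ideality (shape, size dispersity, coatings).
A green suite therefore establishes internal correctness of the forward
model — series, quadrature, sampling, transforms, bookkeeping — not
agreement with any laboratory instrument. Validation against measured
sphere spectra requires lab data and is intentionally outside the test
surface.

Default "stated world" parameters used by demos and tests: the three-sphere
demo scene (2-µm-diameter spheres, 2-µm gaps, 0.2-NA condenser), the
convergence study (3-µm-diameter sphere — the source phrase "3 µm particle"
is read as a diameter, the standard microsphere phrasing — λ = 2.5 µm,
0.8 NA, probe on the axial surface point), instrument-style NA pairs
(0.34, 0.62), and M = 400 MC samples. The null-scatterer MC tolerance of
1e-3 at M = 2000 reflects the measured stratified-sampling error
(~1e-4–3e-4 near focus) with headroom; it is a property of the stated
world, not a tuned number.

## Numerical choices and degenerate inputs

- Tie-breaks: surface points to the internal branch; band-pass boundary
  frequencies pass; d = a samples the internal table.
- $r = 0$: only $l = 0$ contributes ($j_l(0) = \delta_{l0}$); no special
  casing needed beyond $j$ at the origin.
- Legendre evaluation is the three-term recurrence (4 flops/order), exact
  at endpoints; aperture coefficients reuse it at the annulus angles.
- Downward-recurrence overflow is handled by rescaling the running pair
  and the already-stored column by 1e-250 whenever magnitudes exceed
  1e+250.
- Detector geometry requires `det_pixels` to divide the field resolution;
  violations name the nearest valid value.
- Non-unit directions are normalized with a warning, not an error.
- All products are written as plain text with 17 significant digits, so
  byte-identical reruns are a meaningful determinism check (asserted via
  file hashes).

## Known limitations

- No inter-sphere coupling (single scattering); no coated or non-spherical
  particles; no substrate.
- Scalar model: no polarization, no high-NA vector effects.
- No detector noise model; no instrument spectral response or
  interferogram apodization — spectra are computed at exactly the
  requested wavelengths.
- Uniform aperture apodization in the closed-form incident field; other
  apodizations would enter through weighted MC sampling, which the
  sampler's structure permits but the current interface does not expose.
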