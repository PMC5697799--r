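Package: miescope
Title: Forward Simulation of Broadband Mie Scattering in Focused-Beam Microscopy
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates broadband scalar electromagnetic fields focused by
    annular condenser optics, scattered by micro-spheres anywhere in the
    focal volume, and imaged through a band-limiting objective onto a
    detector. Provides Mie scattering coefficients, closed-form focused
    fields for annular apertures, Monte-Carlo aperture integration with
    stratified sampling, Fourier-optics image formation (intensity and
    absorbance images, per-pixel absorbance spectra, extended incoherent
    sources), sphere-surface field meshes, and Kramers-Kronig derivation
    of complex refractive-index spectra from absorbance measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
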