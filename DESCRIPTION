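Package: vibronic
Title: Vibronic Electron-Transfer Spectra from Harmonic State Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models electron-transfer vibronic absorption and emission
    spectra of small molecules (odorants in particular) from pairs of
    harmonic electronic-state models.  Provides mass-weighted Kabsch
    alignment, projection of inter-state geometry displacements onto
    normal modes, Duschinsky rotation matrices, Huang-Rhys factors and
    per-mode reorganization-energy partitioning, Franck-Condon factors
    (generalized-Laguerre closed form, Poisson limit, and an independent
    quadrature oracle), stick-spectrum synthesis with Gaussian
    convolution, inelastic electron tunneling intensities, and windowed
    band-overlap comparison between spectra.  Includes synthetic fixture
    generators with analytically known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
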