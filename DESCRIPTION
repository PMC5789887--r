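Package: qensbilayer
Title: Quasielastic Neutron Scattering and Trajectory Analysis of Lipid
    Bilayer Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models and fitting machinery for the dynamics of
    dioctadecyldimethylammonium bromide (DODAB) bilayers across their
    coagel, gel and fluid phases, as probed by backscattering
    quasielastic neutron scattering (QENS), fixed elastic window scans
    (FEWS) and molecular-dynamics trajectories.  Provides closed-form and
    numerically evaluated incoherent scattering laws (uniaxial jump
    rotation on a circle, methyl three-fold reorientation, localized
    translational diffusion in spheres with linearly distributed radii
    and diffusivities), their elastic incoherent structure factors and
    model half-widths; per-Q two-Lorentzian spectral decomposition with
    resolution convolution; mean-squared-displacement extraction and
    transition detection from elastic scans; Fickian and Arrhenius
    analysis of lateral diffusion; incoherent intermediate scattering
    functions, three-process decay fits, C-H order parameters and
    gauche/trans dihedral statistics from particle trajectories; and
    seeded synthetic-data generators with the exact statistical
    structure the analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
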