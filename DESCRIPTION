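Package: lobehf
Title: Linear-Scaling Hartree-Fock with Gaussian Lobe Basis Functions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: All-electron restricted Hartree-Fock for biomolecular systems
    using Gaussian lobe basis functions, in which p-type orbitals are built
    from signed, displaced s-Gaussians so that every one- and two-electron
    integral reduces to the same s-type expression.  Electron-repulsion
    integrals are screened by a density-relevance criterion (the integral of
    the absolute orbital-pair product) and by a smooth distance cut-off on
    the Coulomb interaction, giving near-linear scaling.  Large structures
    are handled by a divide-and-conquer partition into core+buffer
    subsystems with chemically informed hydrogen capping and density-matrix
    merging.  On top of the solver the package provides real-time
    time-dependent Hartree-Fock absorption spectra and an atomic-energy
    pipeline for assessing predicted protein structures against per-residue
    confidence scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    signal,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
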