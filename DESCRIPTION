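Package: ybdosim
Title: Monte Carlo Dosimetry of an HDR Ytterbium-169 Brachytherapy Source
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale Monte Carlo photon transport and TG-43U1/HEBD dosimetric
    characterization of a high-dose-rate ytterbium-169 brachytherapy seed
    (Model M42 geometry). Simulates primary and scattered photons from the
    encapsulated source through a spherical water phantom or a vacuum/air-ring
    air-kerma geometry, scores collision kerma on a spherical-shell by
    polar-cone detector grid, and extracts the standard two-dimensional dose
    formalism parameters: line-source geometry function, radial dose function,
    anisotropy function, air-kerma strength, dose-rate constant, and the
    fifth-order radial polynomial fit. Ships the published polar dose-rate and
    parameter tables for the same source model as machine-readable fixtures,
    plus a synthetic dose-table generator with known parameters for validating
    the extraction pipeline without transport.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
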