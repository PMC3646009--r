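Package: srpatch
Title: Surface Conservation Patches and Essential Dynamics of Spectrin-Repeat Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structural analysis of spectrin-repeat (SR) three-helix bundle
    models. Computes solvent-accessible surface area with a deterministic
    Shrake-Rupley engine and classifies residues as buried or exposed against
    an Ala-Xxx-Ala reference; merges ConSurf-style conservation grades with
    burial classes and detects putative binding sites (pbs) as conserved,
    exposed residues with more than five conserved, exposed C-alpha
    neighbours within 10 Angstrom; assigns secondary structure with a
    Kabsch-Sander hydrogen-bond model and applies helical-content and
    Z-score model-quality gates; performs essential-dynamics analysis of
    coordinate ensembles (Kabsch superposition, RMSF, C-alpha covariance
    PCA, eigenvector subspace overlap, correlated motions, porcupine
    export); and generates synthetic three-helix bundles, planted
    conservation tables and mode-driven ensembles so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
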