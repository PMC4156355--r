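Package: hfstrand
Title: Transmural Strand Simulation of the Failing Human Ventricle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation of electrical propagation in one-dimensional
    transmural strands of human ventricular myocardium under heart-failure
    remodeling. Implements the Grandi-Pasqualini-Bers and O'Hara-Rudy human
    ventricular action-potential models and the MacCannell active-fibroblast
    model behind a uniform stepping interface, homogeneous and transmurally
    heterogeneous heart-failure ionic remodeling profiles, seeded diffuse and
    patchy fibrosis layout generation, an operator-split monodomain cable
    solver with implicit diffusion, S1-S2 refractory-period search, and a
    biomarker suite (APD90, repolarization time, transmural dispersion of
    repolarization, calcium-transient metrics, conduction velocity, and the
    safety factor for conduction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
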