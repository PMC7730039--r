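Package: osseoheal
Title: Mechano-Regulatory Simulation of Peri-Implant Bone Healing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates tissue differentiation around dental implants with a
    mechano-regulatory algorithm. A two-dimensional axisymmetric poroelastic
    (Biot consolidation) finite-element solver computes octahedral shear
    strain and interstitial fluid velocity in the healing callus; a scalar
    stimulus maps these to tissue phenotypes (fibrous tissue, cartilage,
    immature and mature bone, resorption); mesenchymal stem-cell invasion is
    modelled as diffusion from the callus boundary; element properties are
    blended with cell concentration and smoothed over a moving window. The
    package generates parametric healing-chamber (thread) geometries,
    iterates daily healing steps, and scores designs by bone-implant contact
    (BIC) and bone area (BA) histomorphometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
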