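Package: dccsim
Title: Biphasic Finite-Element Simulation of Decompressive Craniectomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-strain, biphasic (poroelastic) finite-element modelling of
    post-traumatic brain swelling and decompressive craniectomy (DCC). The brain
    is a neo-Hookean solid skeleton saturated by interstitial fluid; swelling is
    imposed through a multiplicative growth decomposition of the deformation
    gradient, interstitial flow follows Darcy's law with Starling vascular and
    lymphatic exchange, and the coupled equilibrium problem is discretized with
    mixed quadratic/linear Lagrange tetrahedral elements. The package generates
    idealized ellipsoidal skull/brain geometries with parametric craniectomy
    openings (unilateral circular, bifrontal, bifrontal with midline bar), runs
    the two-step closed-skull/open-skull DCC procedure, and reports
    herniated-volume-versus-ICP planning curves, midline shift and tissue
    stress summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
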