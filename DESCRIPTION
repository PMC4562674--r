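Package: fibrosim
Title: Spatial Simulation of Idiopathic Pulmonary Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A mechanistic simulator of idiopathic pulmonary fibrosis (IPF)
    progression in lung tissue. The model couples fifteen interacting
    cell populations and cytokines (M1/M2 macrophages, alveolar epithelial
    cells, fibroblasts, myofibroblasts, extracellular matrix, MCP-1, PDGF,
    TGF-beta, MMP, TIMP, TNF-alpha, IL-13 and a derived scar density)
    through a reaction-diffusion-chemotaxis system posed on a homogenized
    alveolar geometry. The package computes the effective diffusion tensor
    of the perforated alveolar unit cell, calibrates kinetic parameters to
    a healthy homeostatic baseline, integrates the disease dynamics from a
    damaged epithelial region on a 3-D grid, and runs comparative in-silico
    trials of anti-fibrotic drug regimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
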