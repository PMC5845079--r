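Package: isletsim
Title: Off-Lattice Cell-Based Simulation of Tumor Islets, Stromal Collagen and T-Cell Infiltration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-stochastic, off-lattice, center-based model of a pancreatic
    tumor islet in two dimensions. Epithelial and cancer cells communicate
    through substrate strain-energy density and migrate by mechanotaxis with
    additive random walk; contacting cells repel through an invagination
    strain-energy term; division, anoikis, mutation, T-cell engulfment and
    T-cell death are memoryless stochastic events gated by strain energy and
    growth clocks. T lymphocytes infiltrate along the gradient of a
    steady-state chemokine field secreted by cancer cells, attenuated
    radially by an anisotropic stromal collagen annulus described by an
    orientation tensor. Includes an Euler-Maruyama integrator with adaptive
    time step, a scenario runner with replicate statistics and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
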