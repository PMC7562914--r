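Package: atherosim
Title: Multi-Level Simulation of Atherosclerotic Plaque Growth in Coronary Arteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates atherosclerotic plaque growth on idealized coronary
    segments through three coupled levels: steady incompressible Newtonian
    blood flow in the lumen with evaluation of the endothelial shear stress
    field, transmural plasma filtration through the porous arterial wall with
    shear- and nitric-oxide-regulated Kedem-Katchalsky endothelial fluxes, a
    ten-species convection-diffusion-reaction network for lipoprotein
    infiltration, LDL oxidation, the monocyte-macrophage-foam-cell cascade,
    cytokine-driven smooth muscle cell phenotype switching and collagen
    turnover, and finally strain-based wall thickening driven by the
    accumulated plaque volume. Includes a synthetic artery generator
    (straight or stenosed axisymmetric segments), cross-section and 3 mm
    sub-segment morphometrics (lumen area, wall area, plaque burden), VTK/STL
    export, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
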