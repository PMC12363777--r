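Package: corneacpm
Title: Cellular Potts Simulation of Corneal Epithelial Homeostasis, Injury
    and Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-dimensional Cellular Potts (Glazier-Graner-Hogeweg)
    agent-based model of the corneal epithelium. Limbal epithelial stem
    cells, basal, wing and superficial cells evolve on a 200x90 voxel
    lattice by Metropolis pixel-copy dynamics under contact, volume,
    surface, chemotaxis and adhesion-spring energies, coupled to a
    reaction-diffusion epidermal growth factor field with cell-type
    dependent diffusion. Rule-based growth (Hill kinetics in EGF and
    crowding pressure), contact-driven differentiation, volume-triggered
    mitosis and probabilistic sloughing produce emergent stratification,
    stable tissue thickness, differential limbal/peripheral turnover, and
    depth-dependent wound healing. Injury modules implement circular
    ablation and diffusing-toxicant chemical exposure with slight, mild
    and moderate depth classification, including recurrent-erosion-like
    breakdown after basement-membrane destruction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
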