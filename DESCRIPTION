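Package: pondassembly
Title: Community Assembly Null Models and Greenhouse-Gas Geochemistry for
    Arctic Thermokarst Pond Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of the computational chain used to
    study microbial community assembly in shallow Arctic thermokarst ponds:
    probabilistic amplicon denoising with an explicit PCR (propagating) and
    sequencing (non-propagating) error model, an internal two-parent chimera
    check, Bray-Curtis beta-diversity with PERMANOVA/SIMPER/Mantel wrappers,
    abundance-based Raup-Crick and normalized stochasticity ratio (NST) null
    models including occupancy-stratified NST, betaMNTD/betaNTI phylogenetic
    turnover, and dissolved CO2/CH4 geochemistry (Henry's law, headspace
    equilibration, Box-Cox regression, DOM optical indices). A synthetic-data
    module generates reads, metacommunities, trees and gas tables with known
    ground truth so that every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    Biostrings,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    picante,
    jsonlite,
    optparse
Config/testthat/edition: 3
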