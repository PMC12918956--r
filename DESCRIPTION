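Package: epijam
Title: Collective Dynamics and Jamming Metrics for Epithelial Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification of collective cell dynamics in crowding epithelial
    monolayers: particle image velocimetry, root-mean-square velocity and its
    time course, velocity correlation length, strain-rate decomposition, T1
    neighbor-exchange detection and rates, cell shape morphometrics, sigmoidal
    transition fitting, motility-onset change-point estimation, and the
    rigid-pack scaling null model for the dependence of the T1 rate on tissue
    motility. Includes seeded synthetic-data generators (rigid-pack and fluid
    monolayer regimes, crowding time courses, phantom image pairs and
    fluorescence phantoms) so every stage can be validated against known
    ground truth, plus fluorescence intensity metrics (junction-to-cytoplasm
    contrast, cytoplasmic-to-nuclear ratios, puncta density, control-normalized
    fold changes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
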