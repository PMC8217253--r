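Package: pellifilm
Title: Structural Analysis of Adsorbed Salivary Pellicle Films at Solid-Liquid Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models, fitting routines and seeded synthetic-data
    generators for the four surface techniques used to characterise
    reconstituted salivary pellicles and their modification by surfactants:
    specular neutron reflectometry with slab models, isotopic contrast
    co-refinement and ensemble-MCMC uncertainties; QCM-D viscoelastic
    (Voigt) film fitting with step segmentation and retention ratios;
    null-ellipsometry film inversion and de Feijter adsorbed mass; and
    AFM force-volume analysis of exponential steric repulsion (calibration,
    Hertz contact point, decay-length distributions, condition fold changes).
    Every stage is verifiable by parameter recovery on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
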