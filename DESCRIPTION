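Package: pleurasim
Title: Virtual-Patient Simulation of Pleural Effusion and Therapeutic
    Thoracentesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A lumped-parameter virtual patient for studying respiratory
    mechanics, alveolar gas exchange and pulmonary perfusion under large
    unilateral pleural effusion and its stepwise therapeutic drainage.
    The respiratory system is modelled as a network of compliant and
    resistive compartments (rib cage, mediastinum, two hemidiaphragms,
    abdomen, airways and up to hundreds of gravity-stacked lung layers
    per side) driven by a tidal-volume-regulated muscle driver; pleural
    fluid adds a hydrostatic pleural-pressure gradient that collapses
    dependent lung layers with recruitment hysteresis.  The package
    also implements the accompanying manometry analysis pipeline:
    breath segmentation, flow integration, pleural pressure-volume loop
    construction, lean and figure-eight classification, pendelluft
    quantification, amplitude statistics and two-stage trend slopes,
    together with a seeded generator of synthetic 25 Hz manometry and
    spirometry sessions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
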