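Package: hspfit
Title: Hansen Solubility Parameter Spheres and Binary Solvent Mixture
    Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the Hansen solubility parameter (HSP) workflow used
    in rational solvent selection for poorly water-soluble solutes such as
    polyphenols: classification of solvents as good or bad from equilibrium
    solubility data, constrained evolutionary fitting of a solute's Hansen
    sphere (centre and interaction radius), relative energy difference (RED)
    diagnostics against a curated literature table of solvent HSPs, and
    prediction of synergistic solubility enhancement and of the composition
    of maximum solubility in binary solvent mixtures from RED profiles over
    mole fraction.  A seeded synthetic-data generator supports end-to-end
    validation of the full solubility-to-sphere pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
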