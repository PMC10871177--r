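Package: memorder
Title: Monolayer and Bilayer Ordering Analysis for Sterol- and
    Hopanoid-Containing Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how ordering lipids such as cholesterol and the
    bacterial hopanoid diplopterol condense phospholipids with different
    acyl-chain double-bond positions.  Implements Langmuir monolayer
    thermodynamics (replicate averaging, the condensing effect with
    first-order error propagation, excess free energy of mixing by
    pressure integration, and regression-based MANOVA comparison of
    isotherm groups), bilayer trajectory observables (deuterium order
    parameter profiles, membrane-normal depth distributions and their
    overlap, terpenoid tilt angles, and periodic Voronoi area per lipid),
    and cell-assay statistics (phenol-red growth-rate extraction,
    osmotic-lysis fraction normalization, and one-way ANOVA with Tukey
    post-hoc tests).  Ships seeded synthetic-data generators with known
    ground truth so every analysis stage is testable without laboratory
    or molecular-dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    deldir,
    bio3d,
    yaml,
    jsonlite,
    withr
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
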