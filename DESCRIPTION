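Package: osteoload
Title: Internal Loads in Plated Metacarpal Osteotomies from
    Displacement-Driven Finite Element Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse determination of the internal loads carried by a plate
    osteosynthesis bridging a 3 mm mid-diaphyseal metacarpal osteotomy during
    simulated, non-weight-bearing rehabilitation exercises. Provides a
    deterministic quadratic-tetrahedral mesher for an idealized
    bone-plate-screw construct, a small-strain linear-elastic finite element
    solver with rigid screw-tie constraints, free-body extraction of the six
    section loads at a cut plane through the plate, normalized-trajectory
    processing onto a common reporting grid, a heteroscedasticity-aware
    statistics chain (Welch ANOVA with Games-Howell post hoc), a safety-margin
    assessment of an adhesive fixation patch against published flexural
    capacities, and a synthetic construct/cohort generator so the whole
    pipeline runs without any experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
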