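Package: seedkin
Title: Seeded Amyloid Aggregation Kinetics and Active-Learning Inhibitor Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for quantifying small-molecule inhibition of
    seeded tau aggregation. Simulates and globally fits two-moment amyloid
    aggregation models (secondary nucleation, saturating secondary nucleation,
    fragmentation), extracts sigmoid half-times and half-time scaling
    exponents, deconvolves inhibitor mechanism (secondary nucleation versus
    elongation) from dose series, fits one-site fibril-binding titrations and
    kinetic dose-response (KIC50) curves, and runs an iterative
    active-learning screening campaign over a molecular library with a random
    forest plus Gaussian-process surrogate, Tanimoto (Butina) clustering and
    CNS MPO filtering. Includes fully deterministic synthetic-data generators
    with planted ground truth for every assay type.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    ranger,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
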