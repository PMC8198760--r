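Package: g1commit
Title: Single-Cell Analysis of the G1 Competition Between Differentiation
    Commitment and Cell-Cycle Entry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse dual-reporter (PPARG / APC/C-degron)
    single-cell time courses of adipocyte terminal differentiation. Includes a
    stochastic population generator with known ground truth in which each G1
    phase hosts a race between crossing an irreversible PPARG commitment
    threshold and entering the next cell cycle; trace quality-control filters;
    mitosis detection and cell-cycle phase segmentation from the APC/C
    reporter; Gaussian-mixture endpoint classification with false-positive-rate
    constrained commitment-threshold estimation; threshold-aligned ensemble and
    marker-correlation analyses; protein half-life fitting from cycloheximide
    decay series; and a mitogen-by-adipogen stimulus grid census of progenitor
    versus differentiated cell numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    rlang
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
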