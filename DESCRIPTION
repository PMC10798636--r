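Package: growthplast
Title: Proteome Allocation Growth Laws with Plastic Nutrient Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state bacterial growth-law modelling in which the
    nutrient quality of a substrate is a plastic, regulation-determined
    parameter rather than a fixed biochemical constant.  Implements the
    ribosome/catabolic-sector flux balance, the decomposition of nutrient
    quality into a core enzymatic quality and an expression fraction
    (kappa_n = f * kappa_n_star), cAMP-style titration curves of growth
    rate against catabolic-sector induction with their optimum, inference
    of nutrient quality from observed growth rates and titration data,
    a protein-cost integration analysis relating transporter copy number
    to growth rate by rank correlation, and phenotype quantification for
    batch-culture data: semi-log exponential growth-rate fits, diauxic
    lag times by back-extrapolation, CFU-based starvation survival and
    soft-agar motility metrics.  A seeded synthetic-data generator
    produces every input table with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
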