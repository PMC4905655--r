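Package: scLineagePower
Title: Feasibility and Power Analysis for Single-Cell Lineage Questions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation framework for assessing how single-cell somatic
    mutation data quality and quantity determine the ability to answer cell
    lineage questions.  Simulates short-tandem-repeat (stepwise mutation
    model) and single-nucleotide-variant accumulation along lineage
    genealogies, distorts the signal with calibrated allele-dropout and
    genotyping-noise models, fits per-sample/per-locus dropout probabilities
    from binary signal tables by maximum likelihood (simulated annealing),
    reconstructs triplet topologies with an absolute distance on shared
    loci, tests for depth differences and independent subclones, and maps
    Monte-Carlo statistical power over (cells x loci) designs with linear
    sequencing-cost optimization along the 95% power contour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
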