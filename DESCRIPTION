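Package: matriline
Title: Extinction of Matrilineal Mitochondrial DNA Lineages via Branching
    Processes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the persistence of a maternally inherited mitochondrial
    DNA line founded by a single female -- for example a donor mtDNA line
    introduced by mitochondrial replacement therapy -- as a Galton-Watson
    branching process on the number of daughters per woman. Provides
    offspring-distribution constructors (empirical, parametric, and a
    census-like synthetic completed-fertility law with binomial sex-ratio
    thinning), exact probability-generating-function analytics (extinction
    probability, per-generation extinction curve, mean time to extinction,
    quantiles), seeded Monte-Carlo lineage simulation with censoring, a
    population carrier-burden estimator for pathogenic mtDNA mutations, and
    TSV/JSON input and output with a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
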