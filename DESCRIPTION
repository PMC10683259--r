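Package: methrisk
Title: Multidimensional Maternal Risk Profiles and Genome-Wide DNA
    Methylation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Context-based analysis pipeline linking multifactorial
    maternal risk profiles to genome-wide DNA-methylation patterns and
    child cardiometabolic and neurocognitive outcomes. Builds composite
    risk profiles by factor analysis of mixed data (with regularized
    iterative imputation), extracts sparse partial-least-squares
    methylation patterns from beta-value matrices and projects them onto
    new datasets, screens patterns against technical and biological
    confounders by singular value decomposition, models outcomes with
    all-relevant random-forest selection against shadow variables and
    repeated cross-validation, and contextualises pattern CpGs by
    permutation and locus-overlap enrichment against genomic feature
    tracks. Ships a synthetic-cohort generator with planted ground truth
    for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ranger,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
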