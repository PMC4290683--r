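Package: CoCoDiff
Title: Complex-Centric Differential Co-Expression and Transcription
    Factor Influence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds condition-specific protein-protein interaction networks
    weighted by co-expression, extracts protein complexes by Markov
    clustering, quantifies and matches complex-level co-expression between
    two conditions, and infers per-transcription-factor influence
    coefficients with a log-linear model solved by SVD least squares.
    Includes reliability scoring of interaction networks (iterated
    Czekanowski-Dice), Kolmogorov-Smirnov and random-complex null
    comparisons of co-expression distributions, differential-network
    classification, permutation significance for influence coefficients,
    and a synthetic-study generator with planted ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'network.R'
    'mcl.R'
    'complexes.R'
    'matching.R'
    'influence.R'
    'synthetic.R'
    'cli.R'
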