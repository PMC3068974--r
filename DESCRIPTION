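Package: survscan
Title: Genome-Wide Survival Association Scans for Copy-Number Microarray Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scans genome-ordered SNP-array copy-number profiles for
    association with censored survival outcomes. Copy numbers are
    locally median-smoothed and optionally rescaled so the modal copy
    level is diploid; each tested marker is scored either by the
    k-group log-rank test on Deletion / No-change / Gain groups or by
    the Wald z of a Cox proportional-hazards fit on the continuous copy
    number. Genome-wide significance is assessed by the MaxT permutation
    procedure under either joint permutation of the clinical (time,
    event) pairs or per-sample chromosome-block permutation that
    preserves local marker correlation. Also provides Kaplan-Meier
    comparison of expression-derived sample clusters, a synthetic-data
    generator with planted copy-number/survival effects, and static
    Kaplan-Meier and genome-track plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
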