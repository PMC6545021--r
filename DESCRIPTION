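Package: repdyn
Title: Repeatome Expression and Methylation Dynamics in Pre-Implantation Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for repeat-element (repeatome) dynamics across
    human pre-implantation development from single-cell data. Provides
    counts-per-million normalisation with stage-wise retention filters,
    per-stage variability (CV) and z-score profiling, PCA, promoter repeat
    enrichment scoring with Fisher's exact test, per-repeat DNA-methylation
    quantification from per-CpG bisulfite records with a coverage filter,
    expression-methylation and repeat-module gene correlation analyses, a
    lightweight stage-specific co-expression module assigner, and a fully
    deterministic synthetic-data generator with machine-readable ground truth
    so that every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
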