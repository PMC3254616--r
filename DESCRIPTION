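Package: popgex
Title: Principal Oscillation Pattern Analysis of Gene-Expression Time Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects periodically expressed genes in genome-wide
    expression time courses by principal oscillation pattern (POP)
    analysis. A low-dimensional linear dynamical system is estimated
    from SVD eigengenes, oscillatory modes are extracted from complex
    conjugate eigenvalue pairs of the system matrix, and every gene is
    assigned an oscillation amplitude and phase from its coefficients
    on the oscillation patterns. Includes an ODE-based simulator of
    periodic transcription with mRNA decay for validation, SVD-based
    missing-value imputation, and the statistical machinery (Welch and
    F tests, permutation tests, survival-curve threshold selection,
    circular phase summaries) used to classify cell-cycle genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, graphics, grDevices, S4Vectors,
    pracma, jsonlite, tools
Suggests: testthat (>= 3.0.0)
biocViews: TimeCourse, GeneExpression, CellCycle, Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
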