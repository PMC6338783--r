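Package: enhmeth
Title: Integrative Analysis of Enhancer DNA Methylation in Paired Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for integrative enhancer-methylome analysis of paired
    tumor/non-tumor cohorts: paired differential-methylation calling over
    fixed regions from capture-style coverage, a length-based enrichment
    statistic for differentially methylated regions in annotated functional
    elements, whole-genome-bisulfite-style differentially methylated
    enhancer (DME) calling, screening of enhancer-target pairs for inverse
    methylation-expression coupling, active-enhancer and super-enhancer
    classification from histone-mark signal, bench-assay quantification
    (pyrosequencing percent methylation, delta-delta-Ct fold changes), and
    Kaplan-Meier survival stratification by enhancer hypomethylation. A
    synthetic-cohort generator with planted effects makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
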