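Package: spatialprof
Title: QC, Normalization and Region-Trend Analysis for Digital Spatial
    Profiling of Early Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for GeoMx-style digital spatial profiling
    (DSP) of tissue regions with ordered histology. Implements area-of-
    illumination (AOI) quality control with negative-probe background metrics,
    probe-level outlier filtering (geometric-mean ratio and Grubbs rules),
    negative-probe limit of quantitation, third-quartile (Q3) count
    normalization with cross-cohort merging, single-sample gene-set enrichment
    (ssGSEA) scoring with a panel-applicability filter, gene-set based immune
    cell deconvolution, and differential/trend statistics across ordered
    histological regions (paired and stepwise t-tests, Spearman ordinal trend,
    one-way ANOVA, Benjamini-Hochberg FDR). A negative-binomial synthetic-data
    generator with planted ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
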