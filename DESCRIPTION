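Package: txconcord
Title: Multi-Compound Transcriptomic Concordance and Overlap-Ratio Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparing transcriptomic responses to structurally
    related compounds in a common cell system, as in bisphenol A/F/S exposure
    studies of stem-cell-derived hepatocyte-like cells. Implements
    differential-expression calling on log2 expression matrices (fold-change
    and FDR thresholds), the overlap-ratio statistic for two and three
    deregulated gene sets over a finite probe universe with a Monte-Carlo
    null, Spearman concordance of genome-wide log2 fold-change profiles,
    top-variance principal component analysis, and IC50 estimation from
    percent-of-control concentration-response curves by linear-segment
    interpolation. A seeded synthetic-data generator emulates the study
    design (multiple compounds plus control, replicated arrays, partially
    shared differentially expressed gene sets with correlated effect sizes,
    monotone dose-response curves) so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
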