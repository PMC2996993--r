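Package: raredex
Title: Two-Colour Microarray Differential Expression, qPCR Quantification,
    and Retinoic-Acid-Response-Element Promoter Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis pipeline of dye-swapped two-colour cDNA
    microarray experiments: spot-level quality filtering (flags, saturation,
    signal-to-background), a correlation-based local background subtraction
    decision, MA computation with robust lowess intensity-dependent
    normalization, dye-swap combination, per-gene one-sample t-tests with
    Benjamini-Hochberg false discovery rate control and signed fold-change
    selection, cross-comparison overlap classification and gene-category
    summaries.  Also implements delta-delta-Ct relative quantification for
    qRT-PCR with replicate dispersion and group tests, and an in-silico
    scanner for retinoic acid response elements (direct repeats of the
    PuG(G/T)TCA half-site with DR1, DR2 and DR5 spacers) over aligned
    promoter pairs restricted to cross-species conserved blocks.  A
    synthetic-data module generates spot-level slides, promoter pairs and
    Ct tables with known ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
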