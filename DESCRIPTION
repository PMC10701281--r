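Package: episcope
Title: Antibody Epitope Landscape Profiling from Whole-Proteome Tiled
    Peptide Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hierarchical antibody-binding analysis for high-density
    peptide microarrays that tile a whole proteome with overlapping
    16-mer probes. Provides in-silico probe library design (tiling,
    deduplication, probe-to-protein position maps), intensity
    preprocessing (log2, quantile normalisation, positional sliding-mean
    smoothing), probe/epitope/protein antibody-binding calls combining a
    global z-test with a naive-vs-immune differential t-test via
    Wilkinson's max meta p-value, FDR control, SKATER-style epitope
    segmentation with consensus-sequence extraction, K-of-N
    co-recognition statistics, signal-strength tiers,
    replicate-concordance reports, and orthogonal-validation statistics
    (hypergeometric/binomial enrichment, two-proportion tests,
    variance-component ICC, ELISA positivity calling). Includes a
    synthetic-data generator with a ground-truth manifest for
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    lme4,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
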