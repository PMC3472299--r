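Package: uprflow
Title: Transcriptome and Growth-Kinetics Analysis of Constitutive UPR Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for microarray studies of the fungal unfolded
    protein response (UPR): probe-level summarization (quantile normalization and
    Tukey median polish of perfect-match probes), empirical-Bayes moderated
    t-statistics with Benjamini-Hochberg false discovery rate control, multi-set
    consistency analysis across timepoints, degenerate UPR-element (UPRE) promoter
    motif scanning with one-sided Fisher enrichment tests, Gene Ontology
    over-representation with true-path annotation propagation over the GO DAG, and
    batch-culture growth kinetics (specific growth rate, exponential-to-linear
    breakpoint detection, biomass yield on substrate). Includes a synthetic-data
    generator that emulates a 3-replicate by 4-condition constitutive-UPR design
    with planted differential expression, planted promoter motifs, a planted
    enriched GO term and two-phase growth curves, so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
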