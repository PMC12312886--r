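Package: ramnet
Title: Regulator-Driven Gene Network Inference for Root Meristem Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Infers a transcription-factor-driven gene regulatory network for
    the root apical meristem from zonated bulk RNA-seq, promoter motif scans
    and induction-response gene lists. Provides negative-binomial Wald
    differential expression with a fold-change threshold null, promoter
    extraction with neighbour-overlap truncation, position-weight-matrix
    scanning against a second-order Markov background with exact
    dynamic-programming p-values, weighted co-expression network construction
    (soft thresholding, topological overlap, module detection, eigengenes)
    with permutation-based module-preservation Z statistics, bidirectional
    best-hit orthology, hypergeometric term enrichment, and single-cell
    activity-based edge weighting with two-component Gaussian-mixture
    thresholds. A synthetic-data module generates every input with known
    ground truth so each stage can be benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
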