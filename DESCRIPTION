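Package: ricdiff
Title: Differential RNA-Interactome Capture Analysis
Version: 0.1.0
Authors@R:
    person("mRBPome", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for differential mRNA-binding proteome
    (mRBPome) studies based on RNA-interactome capture with poly(A)
    competition controls and label-free mass-spectrometry quantification
    (TOP3, iBAQ, LFQ). Implements the peptide-count, control-enrichment and
    replicate-presence filter cascade with total-area normalization; an
    unpaired average-pairwise log2 fold-change statistic with a shuffle-based
    null distribution, a fold-change threshold grid and a linear FDR model;
    cross-quantification-method consensus calling; hypergeometric overlap and
    over-representation statistics with Benjamini-Hochberg adjustment; a
    paralog-specialization analysis with an exact Mann-Whitney test; and a
    seeded synthetic-data generator with ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
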