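Package: mycnreg
Title: Integrative Inference of MYCN Regulatory Networks in Neuroblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs transcription-factor regulatory networks around a
    master regulator (MYCN in neuroblastoma) by integrating ChIP-seq binding
    peaks with dual-platform expression correlation. Calls direct activated
    and repressed target genes from promoter binding plus rank correlation on
    two expression platforms, profiles peak-to-TSS distances, tests E-box
    motif usage, infers co-modulators of the master regulator from
    conditional Spearman correlations (Fisher z differences, KS test), scores
    miRNA differential expression with an empirical noise-distribution
    probability after upper-quartile normalization, integrates miRNA-target
    databases into confidence-scored edges, detects three- and four-node
    TF-miRNA feed-forward loops (hypergeometric and PPI permutation tests),
    flags genes convergently targeted by regulated miRNAs, and stratifies
    patients by consensus k-means over the regulated-gene signature with
    Kaplan-Meier/log-rank comparison. Includes a synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
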