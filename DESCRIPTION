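Package: qrescan
Title: QRE Motif Discovery and miRNA Target-Site Proximity in Spliced 3'UTRs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans spliced 3'UTR sequences for the quaking response element
    (QRE) core motif 'ACUAA', maps hits back to genomic coordinates across
    exon junctions, cross-validates them against eCLIP narrowPeak replicates,
    filters miRNA target sites by expression percentile and mirSVR targeting
    score, and reports QRE-miRNA-site pairs lying within a proximity
    threshold, the configuration proposed for RNA-binding-protein versus
    miRNA competition on a shared 3'UTR. Also provides the expression-side
    analyses for a gene panel: detectability, log2 fold changes, per-dataset
    direction calls, a two-of-three cross-dataset consensus caller, a
    patient-versus-sibling comparison and a correlation test, together with a
    deterministic synthetic-data generator that emits truth-annotated
    genome, annotation, peak, site and expression fixtures for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
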