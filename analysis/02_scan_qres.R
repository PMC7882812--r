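#!/usr/bin/env Rscript
# Step 2 — extract spliced 3'UTRs and scan them for the QRE core 'ACUAA'.
#
# Every occurrence is reported (overlaps included), mapped back to genomic
# blocks (junction hits get two blocks) and annotated with the optional
# 'UAAY' half-site. Writes results/qre_hits.tsv and per-gene counts.

suppressMessages(library(qrescan))

fix_dir <- "results/fixture"
genome <- load_genome(file.path(fix_dir, "genome.fa"))
tx <- load_transcripts(file.path(fix_dir, "annotation.gtf"))
utrs <- build_all_utr3(tx, genome)
hits <- scan_all_qres(utrs, qre_config())

cat("transcripts:", length(tx), "| UTRs:", length(utrs),
    "| QRE hits:", nrow(hits),
    "| junction-spanning:", sum(hits$spans_junction),
    "| with half-site:", sum(!is.na(hits$half_site_t_start)), "\n")

write_report_tsv(hits[, setdiff(colnames(hits), "genomic_blocks")],
                 "results/qre_hits.tsv",
                 params = list(core = "ACUAA", half_site = "UAAY"))
counts <- vapply(utrs, count_qres, integer(1L))
write_report_tsv(data.frame(gene = vapply(utrs, function(u) u$region$gene_symbol,
                                          character(1L)),
                            transcript_id = names(counts),
                            qre_count = unname(counts)),
                 "results/qre_counts.tsv")
cat("wrote results/qre_hits.tsv and results/qre_counts.tsv\n")
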