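#!/usr/bin/env Rscript
# Step 3 — filter miRNA target sites and cross-validate QREs with eCLIP.
#
# Sites survive when their miRNA sits in the top 50% of the expression
# table AND the mirSVR-style score is strictly below -1. QRE hits are kept
# when any genomic block overlaps a narrowPeak in >= 1 replicate; support
# in both duplicates is reported as a column, not enforced.

suppressMessages(library(qrescan))

fix_dir <- "results/fixture"
genome <- load_genome(file.path(fix_dir, "genome.fa"))
tx <- load_transcripts(file.path(fix_dir, "annotation.gtf"))
utrs <- build_all_utr3(tx, genome)
hits <- scan_all_qres(utrs)

sites <- load_site_table(file.path(fix_dir, "mirna_sites.tsv"))
expr <- load_expression_table(file.path(fix_dir, "mirna_expression.tsv"))
filtered <- filter_sites(sites, expr, site_filter_config())
audit <- attr(filtered, "audit")
cat("sites:", nrow(sites), "->", nrow(filtered), "after filtering",
    "(", sum(!audit$expressed_rank_pass), "failed expression,",
    sum(!audit$score_pass), "failed score )\n")

peaks <- list(rep1 = load_peaks(file.path(fix_dir, "eclip_rep1.narrowPeak"), "rep1"),
              rep2 = load_peaks(file.path(fix_dir, "eclip_rep2.narrowPeak"), "rep2"))
validated <- validate_qres(hits, peaks, min_replicates = 1L)
cat("QRE hits:", nrow(hits), "->", nrow(validated), "validated;",
    sum(validated$replicate_support == 2L), "supported in both replicates\n")

write_report_tsv(audit, "results/site_filter_audit.tsv",
                 params = list(expression_top_fraction = 0.5, mirsvr_cutoff = -1))
write_report_tsv(validated[, setdiff(colnames(validated), "genomic_blocks")],
                 "results/validated_qres.tsv",
                 params = list(min_replicates = 1))
cat("wrote results/site_filter_audit.tsv and results/validated_qres.tsv\n")
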