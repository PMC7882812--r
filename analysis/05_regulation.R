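#!/usr/bin/env Rscript
# Step 5 — expression-side analyses.
#
# (a) Consensus regulation over the packaged 17-gene call matrix: a gene is
#     called regulated when the same direction appears in >= 2 of the 3
#     monocyte-to-macrophage differentiation datasets.
# (b) The same consensus rule applied to the simulated expression trio.
# (c) Patient-versus-sibling fold changes at the +/- 0.4 log2 threshold.
# (d) Regulator/target correlation across knockdown donors.
# (e) QRE counts joined to fold changes (the no-correlation scatter).

suppressMessages(library(qrescan))

fix_dir <- "results/fixture"

## (a) packaged call matrix
calls <- load_ngc_call_matrix()
cons <- consensus_table(calls, regulation_config(min_support = 2L))
cat(sprintf("packaged matrix: %d genes -> %d Up, %d Down by >=2-of-3 consensus\n",
            nrow(cons), sum(cons$consensus == "Up"), sum(cons$consensus == "Down")))
write_report_tsv(cons, "results/consensus_calls.tsv",
                 params = list(min_support = 2))

## (b) simulated expression trio
cfg <- regulation_config()
ds_files <- c(ds1 = "expr_ds1_rnaseq.tsv", ds2 = "expr_ds2_microarray.tsv",
              ds3 = "expr_ds3_microarray.tsv")
sim_calls <- do.call(rbind, lapply(names(ds_files), function(dn) {
  tb <- load_expression_table(file.path(fix_dir, ds_files[[dn]]))
  mono <- rowMeans(tb[, grep("mono", colnames(tb)), drop = FALSE])
  mac <- rowMeans(tb[, grep("macro", colnames(tb)), drop = FALSE])
  data.frame(gene = rownames(tb), dataset_id = dn,
             log2fc = log2_fold_change(mac, mono, cfg$pseudocount),
             call = call_direction(log2_fold_change(mac, mono, cfg$pseudocount), cfg),
             stringsAsFactors = FALSE)
}))
sim_cons <- consensus_table(sim_calls, cfg)
cat(sprintf("simulated trio: %d Up, %d Down of %d genes\n",
            sum(sim_cons$consensus == "Up"), sum(sim_cons$consensus == "Down"),
            nrow(sim_cons)))
detect <- detectable_genes(load_expression_table(file.path(fix_dir, ds_files[["ds1"]])),
                           unique(sim_calls$gene))
cat(sprintf("detectable in the count dataset: %d / %d panel genes\n",
            length(detect), length(unique(sim_calls$gene))))
write_report_tsv(sim_cons, "results/simulated_consensus.tsv")

## (c) patient vs sibling
pat <- load_expression_table(file.path(fix_dir, "expr_patient.tsv"))
sib <- load_expression_table(file.path(fix_dir, "expr_sibling.tsv"))
pc <- patient_comparison(pat, sib, rownames(pat), regulation_config(pseudocount = 0))
down_both <- names(which(tapply(pc$call == "Down", pc$gene, all)))
cat("patient deficit (Down in both cell states):",
    paste(sort(down_both), collapse = ", "), "\n")
write_report_tsv(pc, "results/patient_comparison.tsv",
                 params = list(lfc_threshold = 0.4))

## (d) regulator/target correlation across donors
donors <- read_report_tsv(file.path(fix_dir, "expr_qki_target_pairs.tsv"))
cr <- qki_correlation(donors$qki, donors$sema7a)
cat(sprintf("QKI~target correlation across %d donors: r = %.3f, p = %.2e\n",
            nrow(donors), cr$r, cr$p))

## (e) QRE counts vs fold change
genome <- load_genome(file.path(fix_dir, "genome.fa"))
utrs <- build_all_utr3(load_transcripts(file.path(fix_dir, "annotation.gtf")), genome)
counts <- tapply(vapply(utrs, count_qres, integer(1L)),
                 vapply(utrs, function(u) u$region$gene_symbol, character(1L)), sum)
scatter <- join_counts_fc(counts, sim_calls[sim_calls$dataset_id == "ds1", ])
write_report_tsv(scatter, "results/qre_count_vs_fc.tsv")
cat(sprintf("QRE-count vs fold-change table: %d genes (results/qre_count_vs_fc.tsv)\n",
            nrow(scatter)))
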