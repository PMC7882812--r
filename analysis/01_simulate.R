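#!/usr/bin/env Rscript
# Step 1 — generate the truth-annotated study fixtures.
#
# Emits a 20-gene genome + annotation with planted QRE cores (one spanning
# an exon junction), miRNA target sites tied to an expression table, eCLIP
# peaks in two replicates, and monocyte/macrophage expression tables with
# planted fold changes. Everything downstream reads from results/fixture.

suppressMessages(library(qrescan))

seed <- 101L
fix_dir <- "results/fixture"

cfg <- sim_config(seed = seed)
study <- simulate_study(cfg, fix_dir)

cat("fixture written to", fix_dir, "\n")
cat("genes:", cfg$n_genes,
    "| planted proximal:", paste(study$truth$planted_proximal_genes, collapse = ", "), "\n")
cat("planted QREs:", length(study$truth$qres),
    "| junction-spanning:",
    sum(vapply(study$truth$qres, `[[`, logical(1L), "spans_junction")), "\n")
cat("miRNA sites:", length(study$truth$sites),
    "| decoy classes:",
    paste(sort(unique(vapply(study$truth$sites, `[[`, character(1L), "class"))),
          collapse = ", "), "\n")
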