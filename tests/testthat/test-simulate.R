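test_that("a fixed seed reproduces every emitted file byte for byte", {
  d1 <- tempfile(); d2 <- tempfile()
  suppressMessages(simulate_study(sim_config(seed = 7), d1))
  suppressMessages(simulate_study(sim_config(seed = 7), d2))
  files <- list.files(d1)
  expect_true(length(files) >= 9L)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  d3 <- tempfile()
  suppressMessages(simulate_study(sim_config(seed = 8), d3))
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("the annotation carries the requested number of transcripts", {
  d <- tempfile()
  suppressMessages(generate_genome_and_annotation(sim_config(seed = 3, n_genes = 12L), d))
  tx <- load_transcripts(file.path(d, "annotation.gtf"))
  expect_equal(length(tx), 12L)
  strands <- vapply(tx, `[[`, character(1L), "strand")
  expect_true(all(strands %in% c("+", "-")))
  expect_true(length(unique(strands)) == 2L)
  # every transcript yields a UTR with at least two exonic blocks
  genome <- load_genome(file.path(d, "genome.fa"))
  utrs <- build_all_utr3(tx, genome)
  expect_equal(length(utrs), 12L)
  expect_true(all(vapply(utrs, function(u) nrow(u$region$blocks), integer(1L)) >= 2L))
})

test_that("planted QREs are recovered by the scanner at their planted positions", {
  d <- tempfile()
  sk <- suppressMessages(generate_genome_and_annotation(sim_config(seed = 5), d))
  genome <- load_genome(file.path(d, "genome.fa"))
  tx <- load_transcripts(file.path(d, "annotation.gtf"))
  utrs <- build_all_utr3(tx, genome)
  hits <- scan_all_qres(utrs)
  for (q in sk$truth_qres) {
    h <- hits[hits$transcript_id == q$transcript_id & hits$t_start == q$utr_t_start, ]
    expect_equal(nrow(h), 1L)
    expect_equal(h$spans_junction, q$spans_junction)
  }
  # the junction-spanning QRE is the first planted gene's
  jq <- Filter(function(q) q$spans_junction, sk$truth_qres)
  expect_equal(length(jq), 1L)
  expect_equal(jq[[1L]]$gene, "GENE001")
  # truth records all surviving UTR occurrences, planted flagged
  occ <- sk$utr_occurrences
  expect_true(all(vapply(sk$truth_qres, function(q)
    any(occ$transcript_id == q$transcript_id & occ$utr_t_start == q$utr_t_start &
          occ$planted), logical(1L))))
})

test_that("decoy features are rejected at their intended stage and no other", {
  out <- run_simulated_study(29)
  truth <- out$study$truth
  res <- out$res
  classes <- truth$gene_classes
  audit <- attr(res$filtered_sites, "audit")
  site_class <- vapply(truth$sites, `[[`, character(1L), "class")
  site_gene <- vapply(truth$sites, `[[`, character(1L), "gene")

  gene_of <- function(cl) site_gene[site_class == cl]
  # expression decoy: fails only the expression criterion
  ge <- gene_of("decoy_expression")
  row <- audit[audit$gene_symbol == ge, ]
  expect_false(row$expressed_rank_pass); expect_true(row$score_pass)
  # score decoy: fails only the score criterion
  gs <- gene_of("decoy_score")
  row <- audit[audit$gene_symbol == gs, ]
  expect_true(row$expressed_rank_pass); expect_false(row$score_pass)
  # distance decoy: survives filtering and validation but pairs nowhere
  gd <- gene_of("decoy_distance")
  expect_true(gd %in% res$filtered_sites$gene_symbol)
  expect_true(gd %in% res$validated$gene_symbol)
  expect_false(gd %in% res$pairs$gene_symbol)
  # no-peak decoy: site survives filtering, QRE never validated
  gn <- gene_of("decoy_nopeak")
  expect_true(gn %in% res$filtered_sites$gene_symbol)
  expect_false(gn %in% res$validated$gene_symbol)
  expect_true(gn %in% res$hits$gene_symbol)
  # planted genes pass every stage
  expect_true(all(truth$planted_proximal_genes %in% res$gene_summary$gene_symbol))
  # QRE-only decoys are scanned but never validated (no peaks in those genes)
  gq <- names(classes)[classes == "decoy_qre"]
  expect_true(all(gq %in% res$hits$gene_symbol))
  expect_false(any(gq %in% res$validated$gene_symbol))
})

test_that("full peak coverage with two replicates gives support 2 on planted QREs", {
  out <- run_simulated_study(12, sim_config(seed = 12, peak_coverage = 1, n_replicates = 2L))
  planted <- out$study$truth$planted_proximal_genes
  v <- out$res$validated
  expect_true(all(v$replicate_support[v$gene_symbol %in% planted] == 2L))
})

test_that("expression tables recover the planted fold changes and consensus", {
  cfg <- sim_config(seed = 31, noise_sd = 0)
  d <- tempfile()
  sk <- suppressMessages(generate_genome_and_annotation(cfg, d))
  et <- generate_expression_tables(cfg, sk, d)
  ds1 <- load_expression_table(file.path(d, "expr_ds1_rnaseq.tsv"))
  lfc1 <- log2_fold_change(ds1$macrophage, ds1$monocyte, 0)
  planted <- names(et$fc_effects$ds1)[et$fc_effects$ds1 == 1]
  expect_true(all(abs(lfc1[rownames(ds1) %in% planted] - 1) < 0.05))
  expect_true(all(abs(lfc1[et$fc_effects$ds1[rownames(ds1)] == 0]) < 0.05))
  # consensus across the three datasets matches the planted directions,
  # including genes regulated in only two of three
  calls <- do.call(rbind, lapply(c("ds1", "ds2", "ds3"), function(dn) {
    tb <- load_expression_table(file.path(
      d, sprintf("expr_%s_%s.tsv", dn, if (dn == "ds1") "rnaseq" else "microarray")))
    mono <- rowMeans(tb[, grep("mono", colnames(tb)), drop = FALSE])
    mac <- rowMeans(tb[, grep("macro", colnames(tb)), drop = FALSE])
    data.frame(gene = rownames(tb), dataset_id = dn,
               call = call_direction(log2_fold_change(mac, mono, 1)),
               stringsAsFactors = FALSE)
  }))
  cons <- consensus_table(calls)
  truth_dir <- ifelse(et$fc_effects$ds1 > 0, "Up",
                      ifelse(et$fc_effects$ds1 < 0, "Down", "None"))
  expect_equal(cons$consensus[match(names(truth_dir), cons$gene)],
               unname(truth_dir))
  two_of_three <- names(et$fc_effects$ds1)[et$fc_effects$ds1 != 0 &
                                             et$fc_effects$ds3 == 0]
  expect_true(length(two_of_three) >= 1L)
  # patient deficit flagged Down in both cell states
  pat <- load_expression_table(file.path(d, "expr_patient.tsv"))
  sib <- load_expression_table(file.path(d, "expr_sibling.tsv"))
  pc <- patient_comparison(pat, sib, et$patient_deficit_genes,
                           regulation_config(pseudocount = 0))
  expect_true(all(pc$call == "Down"))
})

test_that("inconsistent simulation configs are rejected", {
  expect_error(sim_config(n_genes = 5L), "too small")
  expect_error(sim_config(planted_distance = c(5L, 25L)), "\\[0, 20\\)")
  expect_error(sim_config(peak_coverage = 0), "inconsistent")
  expect_error(sim_config(n_replicates = 3L), "1 or 2")
})
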