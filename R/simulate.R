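#' Simulation configuration for truth-annotated fixtures
#'
#' Defines the study conditions the generator emulates: a small panel of
#' multi-exon genes on both strands, each with a spliced multi-block 3'UTR;
#' planted QRE cores (the first planted gene's QRE spans an exon junction);
#' miRNA target sites with mirSVR-style scores tied to an expression table;
#' eCLIP-style peaks in 1-2 replicates; and monocyte/macrophage expression
#' tables with planted log2 fold changes. Decoy genes are constructed to
#' fail exactly one pipeline criterion each (distance >= 20 nt, miRNA below
#' median expression, score >= -1, or no peak overlap).
#'
#' @param seed Integer seed; a fixed seed yields byte-identical output files.
#' @param n_genes Number of genes; must be at least `n_planted_proximal + 4`
#'   (the four decoy classes) `+ n_decoy_qres`.
#' @param exons_per_transcript Integer range (lo, hi) of exons per transcript.
#' @param utr_length Integer range (lo, hi) of 3'UTR lengths in nt.
#' @param fraction_minus_strand Fraction of genes placed on the minus strand.
#' @param n_planted_proximal Genes given a validated-QRE-adjacent,
#'   filter-surviving miRNA site.
#' @param planted_distance Integer range (lo, hi) of planted QRE-site gaps,
#'   all strictly below 20 nt.
#' @param n_decoy_qres Extra genes carrying a QRE with no peak and no site.
#' @param n_decoy_sites Extra filter-surviving sites placed in peak-less
#'   background genes.
#' @param peak_coverage Probability that a peak-bearing QRE is covered in a
#'   given replicate.
#' @param n_replicates Number of eCLIP replicates (1 or 2).
#' @param mirna_expr_range Numeric (lo, hi) for expressed-miRNA values;
#'   low-expression miRNAs are drawn from (1, 10).
#' @param fc_effects Named numeric vector of planted log2 fold changes for
#'   the expression tables; `NULL` plants +1/-1/0 over the gene panel.
#' @param noise_sd SD of the multiplicative log-normal expression noise.
#' @param mask_background Rewrite accidental 'ACUAA' occurrences in all UTRs
#'   (not only peak-bearing ones) so only planted motifs remain.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L,
                       exons_per_transcript = c(2L, 3L),
                       utr_length = c(150L, 300L),
                       fraction_minus_strand = 0.5,
                       n_planted_proximal = 3L,
                       planted_distance = c(3L, 15L),
                       n_decoy_qres = 3L,
                       n_decoy_sites = 3L,
                       peak_coverage = 1.0,
                       n_replicates = 2L,
                       mirna_expr_range = c(100, 1000),
                       fc_effects = NULL,
                       noise_sd = 0.1,
                       mask_background = FALSE) {
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L || seed > 2^31 - 10) stop("seed out of range")
  if (n_replicates < 1L || n_replicates > 2L) stop("n_replicates must be 1 or 2")
  if (any(planted_distance >= 20L) || any(planted_distance < 0L))
    stop("planted_distance must lie in [0, 20)")
  if (n_genes < n_planted_proximal + 4L + n_decoy_qres)
    stop("n_genes too small for the requested planted and decoy features")
  if (peak_coverage <= 0 && n_planted_proximal > 0L)
    stop("peak_coverage 0 is inconsistent with planted proximal genes")
  structure(list(seed = seed, n_genes = as.integer(n_genes),
                 exons_per_transcript = as.integer(exons_per_transcript),
                 utr_length = as.integer(utr_length),
                 fraction_minus_strand = fraction_minus_strand,
                 n_planted_proximal = as.integer(n_planted_proximal),
                 planted_distance = as.integer(planted_distance),
                 n_decoy_qres = as.integer(n_decoy_qres),
                 n_decoy_sites = as.integer(n_decoy_sites),
                 peak_coverage = peak_coverage,
                 n_replicates = as.integer(n_replicates),
                 mirna_expr_range = mirna_expr_range,
                 fc_effects = fc_effects, noise_sd = noise_sd,
                 mask_background = mask_background),
            class = "sim_config")
}

rand_int <- function(lo, hi) if (lo >= hi) as.integer(lo) else
  as.integer(sample(seq.int(lo, hi), 1L))

rna_to_plus_base <- c(A = "A", C = "C", G = "G", U = "T")
rna_complement_plus_base <- c(A = "T", C = "G", G = "C", U = "A")

# overwrite the genomic bases realising RNA `rna` at transcript interval
# [t_start, t_start + nchar(rna)) of `region`; returns the edited sequence
plant_rna <- function(contig_seq, region, t_start, rna) {
  chars <- strsplit(rna, "")[[1L]]
  gpos <- map_to_genome(region, seq.int(t_start, t_start + length(chars) - 1L))
  base <- if (region$strand == "+") rna_to_plus_base[chars]
          else rna_complement_plus_base[chars]
  for (i in seq_along(gpos))
    substr(contig_seq, gpos[i] + 1L, gpos[i] + 1L) <- base[i]
  contig_seq
}

#' Generate genome FASTA, GTF annotation and the truth-table skeleton
#'
#' Lays the genes end to end on one contig with intergenic gaps, builds
#' random background sequence, plants one QRE core per planted/decoy gene
#' (junction-spanning in the first planted gene), and removes accidental
#' 'ACUAA' occurrences from the UTRs of genes that will carry peaks so the
#' planted truth is exact by construction (all UTRs when
#' `mask_background = TRUE`). Every remaining UTR occurrence, planted or
#' natural, is recorded in the truth skeleton.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed); writes `genome.fa` and
#'   `annotation.gtf`.
#' @return Invisible skeleton list: `genome`, transcript/UTR regions, gene
#'   classes and the truth entries accumulated so far.
#' @export
generate_genome_and_annotation <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  contig <- "chrS"
  n <- cfg$n_genes
  classes <- rep("background", n)
  classes[seq_len(cfg$n_planted_proximal)] <- "planted"
  decoy_classes <- c("decoy_distance", "decoy_expression", "decoy_score", "decoy_nopeak")
  classes[cfg$n_planted_proximal + seq_along(decoy_classes)] <- decoy_classes
  if (cfg$n_decoy_qres > 0L)
    classes[cfg$n_planted_proximal + 4L + seq_len(cfg$n_decoy_qres)] <- "decoy_qre"

  offset <- 500L
  gtf <- character(0)
  seq_parts <- list(random_dna(500L))
  full_regions <- list(); utr_regions <- list(); utr_gtf_flags <- logical(n)
  for (i in seq_len(n)) {
    gid <- sprintf("SIMG%03d", i); tid <- sprintf("SIMT%03d", i)
    sym <- sprintf("GENE%03d", i)
    strand <- if (stats::runif(1) < cfg$fraction_minus_strand) "-" else "+"
    n_ex <- rand_int(max(2L, cfg$exons_per_transcript[1L]), cfg$exons_per_transcript[2L])
    utr_len <- rand_int(cfg$utr_length[1L], cfg$utr_length[2L])
    # transcript-order exon widths; the UTR must span the last junction with
    # >= 60 nt in the terminal exon and >= 40 in the one before it
    # terminal exon holds QRE + site + the widest decoy gap: >= 80 nt
    w_last <- rand_int(80L, utr_len - 40L)
    w <- c(if (n_ex > 2L) sapply(seq_len(n_ex - 2L), function(.) rand_int(120L, 250L)),
           rand_int(max(120L, utr_len - w_last + 40L), max(250L, utr_len - w_last + 120L)),
           w_last)
    introns <- sapply(seq_len(n_ex - 1L), function(.) rand_int(80L, 200L))
    v <- if (strand == "+") w else rev(w)                 # genomic-order widths
    iv <- if (strand == "+") introns else rev(introns)
    starts <- offset + cumsum(c(0L, head(v, -1L) + iv))
    blocks <- cbind(start = starts, end = starts + v)
    region <- spliced_region(tid, gid, sym, contig, strand, blocks)
    L <- region$length
    cds_span <- c(30L, L - utr_len)
    cds_blocks <- map_interval_to_genome(region, cds_span[1L], cds_span[2L])
    utr_blocks <- map_interval_to_genome(region, L - utr_len, L)
    utr_region <- spliced_region(tid, gid, sym, contig, strand, utr_blocks)
    gene_len <- max(blocks[, 2L]) - offset
    seq_parts[[length(seq_parts) + 1L]] <- random_dna(gene_len)
    seq_parts[[length(seq_parts) + 1L]] <- random_dna(400L)  # intergenic gap
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";', gid, tid, sym)
    emit <- function(type, m) sprintf("%s\tqrescan_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                      contig, type, m[, 1L] + 1L, m[, 2L], strand, attrs)
    gtf <- c(gtf, emit("exon", blocks), emit("CDS", cds_blocks))
    utr_gtf_flags[i] <- i %% 2L == 0L   # half the genes get explicit UTR rows
    if (utr_gtf_flags[i]) gtf <- c(gtf, emit("three_prime_utr", utr_blocks))
    full_regions[[tid]] <- region
    utr_regions[[tid]] <- utr_region
    offset <- max(blocks[, 2L]) + 400L
  }
  genome_seq <- paste(unlist(seq_parts), collapse = "")

  # plant QREs: transcript position within the UTR region
  qre_classes <- c("planted", decoy_classes, "decoy_qre")
  truth_qres <- list()
  tids <- names(full_regions)
  for (i in seq_len(n)) {
    if (!classes[i] %in% qre_classes) next
    ur <- utr_regions[[tids[i]]]
    j <- junction_t_pos(ur)   # transcript offset of the terminal UTR block
    t_start <- if (classes[i] == "planted" && i == 1L) j - 2L
               else j + rand_int(5L, 10L)
    genome_seq <- plant_rna(genome_seq, ur, t_start, "ACUAA")
    truth_qres[[length(truth_qres) + 1L]] <- list(
      gene = ur$gene_symbol, transcript_id = ur$transcript_id,
      utr_t_start = t_start, spans_junction = (classes[i] == "planted" && i == 1L),
      class = classes[i])
  }

  # mask accidental cores so the planted truth is exact where peaks will be
  peak_classes <- c("planted", "decoy_distance", "decoy_expression", "decoy_score")
  planted_pos <- split(vapply(truth_qres, `[[`, integer(1L), "utr_t_start"),
                       vapply(truth_qres, `[[`, character(1L), "transcript_id"))
  for (i in seq_len(n)) {
    if (!cfg$mask_background && !classes[i] %in% peak_classes) next
    ur <- utr_regions[[tids[i]]]
    keep <- planted_pos[[tids[i]]]
    repeat {
      rna <- spliced_rna_sequence(ur, stats::setNames(genome_seq, "chrS"))
      acc <- setdiff(scan_core_motif(rna, "ACUAA"), keep)
      if (length(acc) == 0L) break
      genome_seq <- plant_rna(genome_seq, ur, acc[1L] + 2L, "G")
    }
  }

  genome <- stats::setNames(genome_seq, contig)
  writeLines(c(">chrS", chunk_fasta(genome_seq)), file.path(dir, "genome.fa"))
  writeLines(gtf, file.path(dir, "annotation.gtf"))

  # truth records every UTR occurrence that survives, planted or natural
  all_occ <- lapply(tids, function(tid) {
    rna <- spliced_rna_sequence(utr_regions[[tid]], genome)
    pos <- scan_core_motif(rna, "ACUAA")
    if (length(pos) == 0L) return(NULL)
    data.frame(transcript_id = tid, gene = utr_regions[[tid]]$gene_symbol,
               utr_t_start = pos,
               planted = pos %in% planted_pos[[tid]],
               stringsAsFactors = FALSE)
  })
  invisible(list(cfg = cfg, dir = dir, contig = contig, genome = genome,
                 classes = classes, full_regions = full_regions,
                 utr_regions = utr_regions, truth_qres = truth_qres,
                 utr_occurrences = do.call(rbind, all_occ)))
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                  collapse = "")

chunk_fasta <- function(s, width = 70L) {
  starts <- seq.int(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}

# transcript offset (within the UTR region) of its 3'-terminal block
junction_t_pos <- function(ur) {
  widths <- ur$blocks[, 2L] - ur$blocks[, 1L]
  term <- if (ur$strand == "+") length(widths) else 1L
  ur$length - widths[term]
}

#' Plant miRNA sites, eCLIP peaks and miRNA expression; finalise the truth
#'
#' Sites are placed in the terminal UTR exon downstream of each gene's QRE
#' at a controlled genomic gap; decoys violate exactly one criterion each.
#' Peaks cover the QREs of the peak-bearing classes in each replicate with
#' probability `peak_coverage`, plus intergenic noise peaks that avoid all
#' QREs. The miRNA expression table is balanced so expressed miRNAs sit
#' strictly above, and low ones strictly below, the table median.
#'
#' @param cfg A [sim_config()].
#' @param skeleton Result of [generate_genome_and_annotation()].
#' @return Invisible truth list (also written as `truth.json`); files
#'   `mirna_sites.tsv`, `mirna_expression.tsv` and
#'   `eclip_rep<k>.narrowPeak` appear in the skeleton's directory.
#' @export
plant_regulatory_features <- function(cfg, skeleton) {
  set.seed(cfg$seed + 1L)
  dir <- skeleton$dir
  classes <- skeleton$classes
  tids <- names(skeleton$utr_regions)
  qre_by_tid <- list()
  for (q in skeleton$truth_qres) qre_by_tid[[q$transcript_id]] <- q

  sites <- list(); mir_high <- character(0); mir_low <- character(0)
  truth_sites <- list(); mir_n <- 0L
  site_w <- 22L
  add_site <- function(tid, gap, score, expressed, class) {
    ur <- skeleton$utr_regions[[tid]]
    q <- qre_by_tid[[tid]]
    mir_n <<- mir_n + 1L
    mid <- sprintf("miR-%03d", mir_n)
    t0 <- q$utr_t_start + 5L + gap
    m <- map_interval_to_genome(ur, t0, t0 + site_w)
    if (nrow(m) != 1L) stop("internal: planted site crosses a junction")
    sites[[length(sites) + 1L]] <<- data.frame(
      mirna_id = mid, contig = ur$contig, start = m[1L, 1L], end = m[1L, 2L],
      strand = ur$strand, gene = ur$gene_symbol, transcript_id = tid,
      mirsvr_score = score, stringsAsFactors = FALSE)
    if (expressed) mir_high <<- c(mir_high, mid) else mir_low <<- c(mir_low, mid)
    truth_sites[[length(truth_sites) + 1L]] <<- list(
      mirna_id = mid, gene = ur$gene_symbol, score = score,
      expressed = expressed, planted_gap_nt = gap, class = class)
  }
  for (i in seq_along(classes)) {
    tid <- tids[i]
    switch(classes[i],
      planted = add_site(tid, rand_int(cfg$planted_distance[1L], cfg$planted_distance[2L]),
                         round(stats::runif(1, -2.5, -1.2), 2), TRUE, "planted"),
      decoy_distance = add_site(tid, rand_int(25L, 35L), -1.5, TRUE, "decoy_distance"),
      decoy_expression = add_site(tid, rand_int(cfg$planted_distance[1L], cfg$planted_distance[2L]),
                                  -1.5, FALSE, "decoy_expression"),
      decoy_score = add_site(tid, rand_int(cfg$planted_distance[1L], cfg$planted_distance[2L]),
                             -0.5, TRUE, "decoy_score"),
      NULL)
  }
  # the no-peak decoy carries a fully passing site; only validation fails
  nopeak_tid <- tids[classes == "decoy_nopeak"]
  if (length(nopeak_tid)) add_site(nopeak_tid[1L],
                                   rand_int(cfg$planted_distance[1L], cfg$planted_distance[2L]),
                                   -1.5, TRUE, "decoy_nopeak")
  # extra passing sites in peak-less background genes (never validated)
  bg <- which(classes == "background")
  for (k in seq_len(min(cfg$n_decoy_sites, length(bg)))) {
    tid <- tids[bg[k]]
    ur <- skeleton$utr_regions[[tid]]
    j <- junction_t_pos(ur)
    mir_n <- mir_n + 1L
    mid <- sprintf("miR-%03d", mir_n)
    t0 <- j + 10L
    m <- map_interval_to_genome(ur, t0, t0 + site_w)
    sites[[length(sites) + 1L]] <- data.frame(
      mirna_id = mid, contig = ur$contig, start = m[1L, 1L], end = m[1L, 2L],
      strand = ur$strand, gene = ur$gene_symbol, transcript_id = tid,
      mirsvr_score = -1.8, stringsAsFactors = FALSE)
    mir_high <- c(mir_high, mid)
    truth_sites[[length(truth_sites) + 1L]] <- list(
      mirna_id = mid, gene = ur$gene_symbol, score = -1.8, expressed = TRUE,
      planted_gap_nt = NA, class = "decoy_site_no_qre")
  }
  site_df <- do.call(rbind, sites)
  utils::write.table(
    site_df[, c("mirna_id", "contig", "start", "end", "strand", "gene",
                "transcript_id", "mirsvr_score")],
    file.path(dir, "mirna_sites.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # balanced expression table: equal numbers above and below the median
  f_hi <- max(0L, length(mir_low) - length(mir_high)) + 8L
  f_lo <- max(0L, length(mir_high) - length(mir_low)) + 8L
  filler_hi <- sprintf("miR-bg-hi-%02d", seq_len(f_hi))
  filler_lo <- sprintf("miR-bg-lo-%02d", seq_len(f_lo))
  hi_ids <- c(mir_high, filler_hi); lo_ids <- c(mir_low, filler_lo)
  expr <- data.frame(
    mirna_id = c(hi_ids, lo_ids),
    monocyte_expr = round(c(stats::runif(length(hi_ids), cfg$mirna_expr_range[1L],
                                         cfg$mirna_expr_range[2L]),
                            stats::runif(length(lo_ids), 1, 10)), 3),
    stringsAsFactors = FALSE)
  expr <- expr[order(expr$mirna_id), ]
  utils::write.table(expr, file.path(dir, "mirna_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # peaks over the QREs of peak-bearing classes, per replicate
  peak_classes <- c("planted", "decoy_distance", "decoy_expression", "decoy_score")
  genome <- skeleton$genome
  truth_peaks <- list()
  peak_lines <- stats::setNames(vector("list", cfg$n_replicates),
                                sprintf("rep%d", seq_len(cfg$n_replicates)))
  pk_n <- 0L
  for (i in seq_along(classes)) {
    if (!classes[i] %in% peak_classes) next
    tid <- tids[i]
    ur <- skeleton$utr_regions[[tid]]
    q <- qre_by_tid[[tid]]
    gb <- map_interval_to_genome(ur, q$utr_t_start, q$utr_t_start + 5L)
    for (r in seq_len(cfg$n_replicates)) {
      if (stats::runif(1) > cfg$peak_coverage) next
      pk_n <- pk_n + 1L
      s <- min(gb[, 1L]) - rand_int(5L, 15L)
      e <- max(gb[, 2L]) + rand_int(5L, 15L)
      peak_lines[[r]] <- c(peak_lines[[r]], sprintf(
        "%s\t%d\t%d\tpeak%03d\t%d\t.\t%.2f\t%.2f\t%.2f\t%d",
        ur$contig, s, e, pk_n, 0L, stats::runif(1, 2, 8),
        stats::runif(1, 5, 30), stats::runif(1, 3, 20), (e - s) %/% 2L))
      truth_peaks[[length(truth_peaks) + 1L]] <- list(
        gene = ur$gene_symbol, replicate = sprintf("rep%d", r),
        name = sprintf("peak%03d", pk_n))
    }
  }
  # intergenic noise peaks (the 500 nt head of the contig carries no genes)
  for (r in seq_len(cfg$n_replicates)) {
    for (k in 1:2) {
      pk_n <- pk_n + 1L
      s <- rand_int(10L, 300L)
      peak_lines[[r]] <- c(peak_lines[[r]], sprintf(
        "%s\t%d\t%d\tpeak%03d\t0\t.\t%.2f\t%.2f\t%.2f\t%d",
        skeleton$contig, s, s + 120L, pk_n, stats::runif(1, 1, 3),
        stats::runif(1, 2, 8), stats::runif(1, 1, 5), 60L))
    }
  }
  for (r in seq_len(cfg$n_replicates))
    writeLines(peak_lines[[r]], file.path(dir, sprintf("eclip_rep%d.narrowPeak", r)))

  truth <- list(
    planted_proximal_genes = sort(vapply(
      skeleton$truth_qres[vapply(skeleton$truth_qres, `[[`, character(1L), "class") == "planted"],
      `[[`, character(1L), "gene")),
    qres = skeleton$truth_qres,
    utr_occurrences = skeleton$utr_occurrences,
    sites = truth_sites,
    peaks = truth_peaks,
    gene_classes = stats::setNames(classes, vapply(skeleton$utr_regions,
                                                   `[[`, character(1L), "gene_symbol")))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

#' Generate monocyte/macrophage expression tables with planted fold changes
#'
#' Emits three pseudo-datasets mirroring a heterogeneous trio — one
#' single-sample count table (RNA-seq-like) and two replicated intensity
#' tables (microarray-like) — plus a patient/sibling pair carrying a planted
#' expression deficit on the regulator-dependent genes, and a donor table of
#' paired regulator/target values with a positive planted slope.
#'
#' Planted log2 fold changes default to +1 for the planted proximal genes,
#' -1 for the decoy genes, 0 elsewhere; every third regulated gene is left
#' unchanged in the third dataset so the two-of-three consensus rule is
#' exercised. Values are `baseline * 2^lfc` with multiplicative log-normal
#' noise (`noise_sd` on the natural-log scale).
#'
#' @param cfg A [sim_config()].
#' @param skeleton Result of [generate_genome_and_annotation()] (for the
#'   gene panel), or a character vector of gene symbols.
#' @param dir Output directory.
#' @return Invisible list with the planted truth: `fc_effects` (per dataset)
#'   and `patient_deficit_genes`.
#' @export
generate_expression_tables <- function(cfg, skeleton, dir) {
  set.seed(cfg$seed + 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- if (is.character(skeleton)) skeleton
           else vapply(skeleton$utr_regions, `[[`, character(1L), "gene_symbol")
  classes <- if (is.character(skeleton)) rep("background", length(panel))
             else skeleton$classes
  lfc <- cfg$fc_effects
  if (is.null(lfc)) {
    lfc <- stats::setNames(rep(0, length(panel)), panel)
    lfc[classes == "planted"] <- 1
    lfc[startsWith(classes, "decoy")] <- -1
  }
  regulated <- names(lfc)[lfc != 0]
  lfc_by_ds <- list(ds1 = lfc, ds2 = lfc, ds3 = lfc)
  drop3 <- regulated[seq_along(regulated) %% 3L == 0L]
  lfc_by_ds$ds3[drop3] <- 0

  baseline <- stats::setNames(round(stats::runif(length(panel), 50, 500)), panel)
  noisy <- function(mu) mu * exp(stats::rnorm(length(mu), 0, cfg$noise_sd))

  # dataset 1: single-sample counts
  ds1 <- data.frame(gene = panel,
                    monocyte = round(noisy(baseline)),
                    macrophage = round(noisy(baseline * 2^lfc_by_ds$ds1)))
  utils::write.table(ds1, file.path(dir, "expr_ds1_rnaseq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # datasets 2-3: replicated intensities
  for (d in c("ds2", "ds3")) {
    tb <- data.frame(gene = panel)
    for (r in 1:3) tb[[sprintf("monocyte_%d", r)]] <- round(noisy(baseline), 3)
    for (r in 1:3) tb[[sprintf("macrophage_%d", r)]] <-
      round(noisy(baseline * 2^lfc_by_ds[[d]]), 3)
    utils::write.table(tb, file.path(dir, sprintf("expr_%s_microarray.tsv", d)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  # patient vs sibling: deficit (log2 -1) on the planted proximal genes
  deficit <- panel[classes == "planted"]
  sib <- cbind(monocyte = noisy(baseline), macrophage = noisy(baseline))
  pat <- cbind(monocyte = noisy(baseline * 2^(-(panel %in% deficit))),
               macrophage = noisy(baseline * 2^(-(panel %in% deficit))))
  utils::write.table(data.frame(gene = panel, round(sib, 3)),
                     file.path(dir, "expr_sibling.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = panel, round(pat, 3)),
                     file.path(dir, "expr_patient.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # paired regulator/target values across donors, planted slope 1
  qki <- stats::runif(12, 0.3, 1.0)
  target <- qki + stats::rnorm(12, 0, cfg$noise_sd / 2)
  utils::write.table(data.frame(donor = sprintf("donor%02d", 1:12),
                                qki = round(qki, 4), sema7a = round(target, 4)),
                     file.path(dir, "expr_qki_target_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fc_effects = lfc_by_ds, patient_deficit_genes = deficit,
                 baseline = baseline))
}

#' Generate a complete truth-annotated fixture set
#'
#' Runs [generate_genome_and_annotation()], [plant_regulatory_features()]
#' and [generate_expression_tables()] under one seed.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @return List with `skeleton`, `truth` and `expression_truth`.
#' @export
simulate_study <- function(cfg, dir) {
  skeleton <- generate_genome_and_annotation(cfg, dir)
  truth <- plant_regulatory_features(cfg, skeleton)
  expr_truth <- generate_expression_tables(cfg, skeleton, dir)
  list(skeleton = skeleton, truth = truth, expression_truth = expr_truth)
}
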