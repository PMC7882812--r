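# shared helpers: tiny deterministic regions, random region generator,
# and a one-call simulated study + pipeline run

two_block_region <- function(strand = "+", blocks = rbind(c(100L, 150L), c(200L, 260L))) {
  spliced_region("t1", "g1", "G1", "chr1", strand, blocks)
}

# random multi-block spliced region; lengths kept small so exhaustive
# per-position checks stay cheap
random_region <- function(max_blocks = 4L, max_width = 60L) {
  n <- sample.int(max_blocks, 1L)
  starts <- integer(n); ends <- integer(n)
  pos <- sample.int(50L, 1L)
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + sample.int(max_width, 1L)
    pos <- ends[i] + sample.int(30L, 1L)   # gap >= 1 so blocks never touch
  }
  spliced_region("t", "g", "G", "c", sample(c("+", "-"), 1L),
                 cbind(starts, ends))
}

# write a minimal GTF from feature rows (1-based closed coordinates)
write_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_row <- function(type, start1, end1, strand = "+", tid = "t1", gid = "g1",
                    sym = NULL, contig = "chr1") {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
  if (!is.null(sym)) attrs <- paste0(attrs, sprintf(' gene_name "%s";', sym))
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s", contig, type, start1, end1, strand, attrs)
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))), path)
  path
}

# generate a full fixture and run the pipeline over it
run_simulated_study <- function(seed, cfg = sim_config(seed = seed), ...) {
  dir <- tempfile("fix")
  st <- suppressMessages(simulate_study(cfg, dir))
  peaks <- file.path(dir, sprintf("eclip_rep%d.narrowPeak", seq_len(cfg$n_replicates)))
  names(peaks) <- sprintf("rep%d", seq_len(cfg$n_replicates))
  rc <- run_config(file.path(dir, "genome.fa"), file.path(dir, "annotation.gtf"),
                   file.path(dir, "mirna_sites.tsv"),
                   file.path(dir, "mirna_expression.tsv"),
                   peaks, tempfile("out"), ...)
  res <- suppressMessages(run_pipeline(rc))
  list(dir = dir, study = st, run_cfg = rc, res = res)
}

# brute-force motif count: check every window
oracle_scan <- function(seq, core = "ACUAA") {
  k <- nchar(core)
  if (nchar(seq) < k) return(integer(0))
  which(vapply(seq_len(nchar(seq) - k + 1L),
               function(i) substr(seq, i, i + k - 1L) == core, logical(1L))) - 1L
}

random_rna <- function(len) paste(sample(c("A", "C", "G", "U", "N"), len,
                                         replace = TRUE,
                                         prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                                  collapse = "")
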