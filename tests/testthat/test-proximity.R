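mk_validated <- function(blocks, gene = "G1", tid = "t1", contig = "c",
                         t_start = 0L, support = 2L) {
  out <- data.frame(transcript_id = tid, gene_id = "g1", gene_symbol = gene,
                    contig = contig, strand = "+", t_start = t_start,
                    t_end = t_start + 5L, core_seq = "ACUAA",
                    spans_junction = nrow(blocks) > 1L,
                    half_site_t_start = NA_integer_,
                    blocks_str = paste(sprintf("%d-%d", blocks[, 1L], blocks[, 2L]),
                                       collapse = ","),
                    stringsAsFactors = FALSE)
  out$genomic_blocks <- list(blocks)
  out$replicate_support <- support
  out
}

mk_fsites <- function(start, end = start + 22L, gene = "G1", contig = "c",
                      mirna = sprintf("miR-%d", seq_along(start))) {
  data.frame(mirna_id = mirna, gene_symbol = gene, transcript_id = NA_character_,
             contig = contig, start = as.integer(start), end = as.integer(end),
             strand = "+", mirsvr_score = -1.5,
             expressed_rank_pass = TRUE, score_pass = TRUE,
             stringsAsFactors = FALSE)
}

test_that("pairs are kept strictly below the distance threshold", {
  q <- mk_validated(rbind(c(1000L, 1005L)))
  near <- find_proximal_pairs(q, mk_fsites(1010L, 1032L))
  expect_equal(nrow(near), 1L)
  expect_equal(near$distance_nt, 5L)
  # exactly 20 nt away: excluded by the strict rule
  at20 <- find_proximal_pairs(q, mk_fsites(1025L, 1047L))
  expect_equal(nrow(at20), 0L)
  at19 <- find_proximal_pairs(q, mk_fsites(1024L, 1046L))
  expect_equal(at19$distance_nt, 19L)
  # overlap counts as distance zero
  ov <- find_proximal_pairs(q, mk_fsites(1003L, 1025L))
  expect_equal(ov$distance_nt, 0L)
})

test_that("pairing requires same gene and same contig", {
  q <- mk_validated(rbind(c(1000L, 1005L)))
  expect_equal(nrow(find_proximal_pairs(q, mk_fsites(1010L, gene = "OTHER"))), 0L)
  expect_equal(nrow(find_proximal_pairs(q, mk_fsites(1010L, contig = "c2"))), 0L)
  # junction QRE: distance is the minimum over its genomic blocks
  qj <- mk_validated(rbind(c(100L, 103L), c(300L, 302L)))
  p <- find_proximal_pairs(qj, mk_fsites(305L))
  expect_equal(p$distance_nt, 3L)
})

test_that("reported distances match a brute-force all-pairs oracle", {
  withr::with_seed(41, {
    qs <- do.call(rbind, lapply(1:10, function(i) {
      s <- sample.int(3000L, 1L)
      mk_validated(rbind(c(s, s + 5L)), tid = sprintf("t%d", i))
    }))
    sites <- mk_fsites(sample.int(3000L, 40L))
    got <- find_proximal_pairs(qs, sites)
    # oracle: every (hit, site) combination, plain integer arithmetic
    n_expected <- 0L
    for (i in seq_len(nrow(qs))) for (j in seq_len(nrow(sites))) {
      b <- qs$genomic_blocks[[i]]
      d <- max(0L, max(b[1L, 1L], sites$start[j]) - min(b[1L, 2L], sites$end[j]))
      if (d < 20L) {
        n_expected <- n_expected + 1L
        row <- got[got$transcript_id == qs$transcript_id[i] &
                     got$mirna_id == sites$mirna_id[j], ]
        expect_equal(row$distance_nt, d)
      }
    }
    expect_equal(nrow(got), n_expected)
    # monotone in the threshold; invariant to input ordering
    wider <- find_proximal_pairs(qs, sites, proximity_config(max_distance_nt = 50L))
    expect_true(nrow(wider) >= nrow(got))
    shuf <- find_proximal_pairs(qs[sample.int(nrow(qs)), ],
                                sites[sample.int(nrow(sites)), ])
    expect_identical(shuf, got)
  })
})

test_that("spliced-space distance agrees with genomic within one exon and spans introns", {
  g <- c(c = paste(rep("A", 1000L), collapse = ""))
  r <- spliced_region("t1", "g1", "G1", "c", "+", rbind(c(100L, 200L), c(400L, 500L)))
  utr <- structure(list(region = r, rna_sequence = spliced_rna_sequence(r, g)),
                   class = "utr3")
  utrs <- list(t1 = utr)
  q <- mk_validated(rbind(c(110L, 115L)), t_start = 10L)
  s_same_exon <- mk_fsites(130L, 152L)
  pg <- find_proximal_pairs(q, s_same_exon)
  ps <- find_proximal_pairs(q, s_same_exon,
                            proximity_config(coordinate_space = "spliced"), utrs)
  expect_equal(pg$distance_nt, ps$distance_nt)
  # site just across the intron: adjacent in transcript space, far in genome
  q_end <- mk_validated(rbind(c(190L, 195L)), t_start = 90L)
  s_next_exon <- mk_fsites(405L, 427L)
  far_genomic <- find_proximal_pairs(q_end, s_next_exon)
  expect_equal(nrow(far_genomic), 0L)
  near_spliced <- find_proximal_pairs(q_end, s_next_exon,
                                      proximity_config(coordinate_space = "spliced"), utrs)
  expect_equal(near_spliced$distance_nt, 10L)
  # spliced mode skips sites outside the UTR blocks
  outside <- mk_fsites(300L, 322L)
  expect_message(
    none <- find_proximal_pairs(q, outside,
                                proximity_config(coordinate_space = "spliced"), utrs),
    "outside")
  expect_equal(nrow(none), 0L)
})

test_that("gene summary aggregates pairs deterministically", {
  q <- mk_validated(rbind(c(1000L, 1005L)))
  p3 <- find_proximal_pairs(q, mk_fsites(c(1010L, 1012L, 1015L)))
  sm <- summarize_genes(p3)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$n_pairs, 3L)
  expect_equal(sm$n_mirnas, 3L)
  expect_equal(sm$best_distance_nt, 5L)
  expect_equal(nrow(summarize_genes(p3[0, ])), 0L)
})
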