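#' Derive the 3'UTR spliced region of a transcript
#'
#' If the annotation carries explicit `three_prime_utr` blocks they are used
#' verbatim. Otherwise the UTR is the exonic territory strictly 3' of the
#' annotated CDS end in transcript orientation (genomic right of the CDS on
#' `+`, genomic left on `-`). The CDS end is taken exactly as annotated; no
#' stop-codon adjustment is applied. Transcripts with neither explicit UTR
#' blocks nor a CDS are skipped with a warning (return `NULL`).
#'
#' @param tx A transcript model from [load_transcripts()].
#' @return A [spliced_region()] covering the 3'UTR, or `NULL` if the
#'   transcript carries no UTR information or the UTR is empty.
#' @export
derive_utr3 <- function(tx) {
  if (is.null(tx$exons)) stop("transcript ", tx$transcript_id, " has no exons")
  blocks <- NULL
  if (!is.null(tx$utr3)) {
    blocks <- tx$utr3
  } else if (!is.null(tx$cds)) {
    cds_lo <- min(tx$cds[, 1L]); cds_hi <- max(tx$cds[, 2L])
    if (cds_lo < min(tx$exons[, 1L]) || cds_hi > max(tx$exons[, 2L]))
      stop("CDS extends beyond exons for transcript ", tx$transcript_id)
    blocks <- if (tx$strand == "+") clip_blocks(tx$exons, cds_hi, NA)
              else clip_blocks(tx$exons, NA, cds_lo)
  } else {
    warning("transcript ", tx$transcript_id,
            " has neither three_prime_utr nor CDS; skipped")
    return(NULL)
  }
  if (is.null(blocks) || nrow(blocks) == 0L) return(NULL)
  spliced_region(tx$transcript_id, tx$gene_id, tx$gene_symbol,
                 tx$contig, tx$strand, blocks)
}

# restrict blocks to [lo, hi) where either bound may be NA (unbounded)
clip_blocks <- function(blocks, lo, hi) {
  s <- blocks[, 1L]; e <- blocks[, 2L]
  if (!is.na(lo)) s <- pmax(s, lo)
  if (!is.na(hi)) e <- pmin(e, hi)
  keep <- s < e
  if (!any(keep)) return(NULL)
  m <- cbind(start = s[keep], end = e[keep])
  storage.mode(m) <- "integer"
  m
}

#' Spliced RNA sequence of a region
#'
#' Concatenates the block sequences in transcript order (reverse-complemented
#' for minus-strand regions), then transcribes T to U. Bases outside
#' `{A,C,G,T,N}` are kept as `N`.
#'
#' @param region A [spliced_region()].
#' @param genome Named character vector from [load_genome()].
#' @return Uppercase RNA string of length `region$length`.
#' @export
spliced_rna_sequence <- function(region, genome) {
  if (!region$contig %in% names(genome))
    stop("contig not in genome: ", region$contig)
  contig_seq <- genome[[region$contig]]
  if (max(region$blocks[, 2L]) > nchar(contig_seq))
    stop("block beyond contig end on ", region$contig)
  parts <- substring(contig_seq, region$blocks[, 1L] + 1L, region$blocks[, 2L])
  dna <- paste(parts, collapse = "")
  dna <- gsub("[^ACGTN]", "N", toupper(dna))
  if (region$strand == "-")
    dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  chartr("T", "U", dna)
}

#' Build a 3'UTR object (region + spliced RNA sequence)
#'
#' @param tx Transcript model from [load_transcripts()].
#' @param genome Named character vector from [load_genome()].
#' @return List of class `utr3` with `region` and `rna_sequence`, or `NULL`
#'   when the transcript has no derivable 3'UTR.
#' @export
build_utr3 <- function(tx, genome) {
  region <- derive_utr3(tx)
  if (is.null(region)) return(NULL)
  structure(list(region = region,
                 rna_sequence = spliced_rna_sequence(region, genome)),
            class = "utr3")
}

#' @export
print.utr3 <- function(x, ...) {
  cat(sprintf("utr3 of %s (%s), %d nt over %d block(s)\n",
              x$region$transcript_id, x$region$gene_symbol,
              x$region$length, nrow(x$region$blocks)))
  invisible(x)
}

#' Build 3'UTRs for every transcript in an annotation
#'
#' @param transcripts List from [load_transcripts()].
#' @param genome Named character vector from [load_genome()].
#' @return Named list of `utr3` objects; transcripts without a derivable UTR
#'   are dropped (with the warning from [derive_utr3()]).
#' @export
build_all_utr3 <- function(transcripts, genome) {
  utrs <- lapply(transcripts, build_utr3, genome = genome)
  utrs[!vapply(utrs, is.null, logical(1L))]
}
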