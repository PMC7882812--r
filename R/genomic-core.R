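#' Genomic interval
#'
#' Constructs a contig- and strand-aware genomic interval in the package's
#' single internal convention: 0-based, half-open `[start, end)`. All
#' coordinate conversions (GTF 1-based closed spans, BED 0-based half-open)
#' happen at the I/O boundary, never here.
#'
#' @param contig Contig (chromosome) identifier, non-empty string.
#' @param start Integer >= 0, 0-based inclusive start.
#' @param end Integer, exclusive end; must satisfy `end > start`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr15", 74702800, 74702950)
#' @export
genomic_interval <- function(contig, start, end, strand = ".") {
  if (!is.character(contig) || length(contig) != 1L || !nzchar(contig))
    stop("contig must be a non-empty string")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("start/end must be integers")
  if (start < 0L) stop("start must be >= 0")
  if (start >= end) stop("empty or inverted interval rejected: [", start, ", ", end, ")")
  if (!strand %in% c("+", "-", ".")) stop("strand must be one of '+', '-', '.'")
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d(%s)>\n", x$contig, x$start, x$end, x$strand))
  invisible(x)
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%d-%d(%s)", x$contig, x$start, x$end, x$strand)
}

#' Width of a genomic interval
#' @param x A `genomic_interval`.
#' @return Integer number of bases covered.
#' @export
interval_width <- function(x) x$end - x$start

#' Gap between two genomic intervals
#'
#' Number of bases strictly between two intervals on the same contig. The
#' proximity rule ("distance less than 20 nucleotides") is evaluated on this
#' quantity: overlapping or book-ended intervals are at distance 0, so a
#' shared or touching base never counts as separation.
#'
#' @param a,b `genomic_interval` objects on the same contig.
#' @return Non-negative integer gap; 0 on overlap or adjacency.
#' @examples
#' interval_gap(genomic_interval("c", 10, 20), genomic_interval("c", 25, 30)) # 5
#' interval_gap(genomic_interval("c", 10, 20), genomic_interval("c", 20, 25)) # 0
#' @export
interval_gap <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  if (a$contig != b$contig)
    stop("interval_gap undefined across contigs: ", a$contig, " vs ", b$contig)
  gap_1d(a$start, a$end, b$start, b$end)
}

# plain-integer gap on half-open spans; shared by the vectorised callers
gap_1d <- function(s1, e1, s2, e2) {
  max(0L, max(s1, s2) - min(e1, e2))
}

#' Do two intervals overlap by at least one base?
#' @param a,b `genomic_interval` objects.
#' @return Logical. Always `FALSE` across contigs; strand is ignored.
#' @export
interval_overlaps <- function(a, b) {
  if (a$contig != b$contig) return(FALSE)
  a$start < b$end && b$start < a$end
}

#' Spliced region: an exon-block coordinate system
#'
#' An ordered set of non-overlapping exonic blocks on one contig defining a
#' transcript-local coordinate system. Transcript coordinate 0 is the 5'-most
#' base in transcript orientation: the leftmost block start on `+`, the
#' rightmost `end - 1` on `-`.
#'
#' @param transcript_id,gene_id,gene_symbol Identifiers carried through to
#'   downstream reports.
#' @param contig Contig identifier shared by all blocks.
#' @param strand `"+"` or `"-"` (unstranded regions are not meaningful here).
#' @param blocks Two-column integer matrix (start, end), 0-based half-open,
#'   rows sorted by ascending genomic start, non-overlapping.
#' @return An object of class `spliced_region` with a `length` field equal to
#'   the summed block widths.
#' @export
spliced_region <- function(transcript_id, gene_id, gene_symbol, contig, strand, blocks) {
  if (!strand %in% c("+", "-")) stop("spliced_region strand must be '+' or '-'")
  blocks <- as.matrix(blocks)
  storage.mode(blocks) <- "integer"
  if (ncol(blocks) != 2L || nrow(blocks) < 1L)
    stop("blocks must be an n x 2 (start, end) matrix with n >= 1")
  colnames(blocks) <- c("start", "end")
  if (any(blocks[, 1L] < 0L) || any(blocks[, 1L] >= blocks[, 2L]))
    stop("each block must satisfy 0 <= start < end")
  if (is.unsorted(blocks[, 1L], strictly = TRUE) && nrow(blocks) > 1L)
    stop("blocks must be sorted by ascending genomic start")
  if (nrow(blocks) > 1L && any(blocks[-nrow(blocks), 2L] > blocks[-1L, 1L]))
    stop("blocks must be non-overlapping")
  len <- sum(blocks[, 2L] - blocks[, 1L])
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 gene_symbol = gene_symbol, contig = contig, strand = strand,
                 blocks = blocks, length = len),
            class = "spliced_region")
}

#' @export
print.spliced_region <- function(x, ...) {
  cat(sprintf("spliced_region %s (%s/%s) %s%s, %d block(s), length %d\n",
              x$transcript_id, x$gene_id, x$gene_symbol, x$contig, x$strand,
              nrow(x$blocks), x$length))
  invisible(x)
}

# block widths in genomic order
block_widths <- function(region) region$blocks[, 2L] - region$blocks[, 1L]

#' Map transcript positions to genomic positions
#'
#' Strand-aware mapping from transcript-local coordinates (0-based along the
#' spliced sequence) to single genomic base positions. Vectorised over
#' `t_pos`.
#'
#' @param region A [spliced_region()].
#' @param t_pos Integer vector, each in `[0, region$length)`.
#' @return Integer vector of 0-based genomic positions on `region$contig`.
#' @examples
#' r <- spliced_region("t", "g", "G", "chr1", "+", rbind(c(100, 150), c(200, 260)))
#' map_to_genome(r, 60) # 210
#' @export
map_to_genome <- function(region, t_pos) {
  stopifnot(inherits(region, "spliced_region"))
  t_pos <- as.integer(t_pos)
  if (length(t_pos) && (anyNA(t_pos) || any(t_pos < 0L) || any(t_pos >= region$length)))
    stop("t_pos out of range [0, ", region$length, ")")
  w <- block_widths(region)
  if (region$strand == "+") {
    tx_starts <- cumsum(c(0L, w))[seq_along(w)]  # transcript offset of each block
    idx <- findInterval(t_pos, tx_starts)
    unname(region$blocks[idx, 1L] + (t_pos - tx_starts[idx]))
  } else {
    # transcript order is reverse genomic order on the minus strand
    w_rev <- rev(w)
    tx_starts <- cumsum(c(0L, w_rev))[seq_along(w_rev)]
    idx_rev <- findInterval(t_pos, tx_starts)
    idx <- nrow(region$blocks) + 1L - idx_rev
    unname(region$blocks[idx, 2L] - 1L - (t_pos - tx_starts[idx_rev]))
  }
}

#' Map genomic positions back to transcript positions
#'
#' Inverse of [map_to_genome()]. Positions falling in introns or outside the
#' region raise an error.
#'
#' @param region A [spliced_region()].
#' @param g_pos Integer vector of 0-based genomic positions within the blocks.
#' @return Integer vector of transcript positions.
#' @export
map_from_genome <- function(region, g_pos) {
  stopifnot(inherits(region, "spliced_region"))
  g_pos <- as.integer(g_pos)
  b <- region$blocks
  idx <- findInterval(g_pos, b[, 1L])
  bad <- idx < 1L | g_pos >= b[pmax(idx, 1L), 2L]
  if (length(g_pos) && any(bad))
    stop("genomic position(s) outside exonic blocks: ",
         paste(g_pos[bad], collapse = ", "))
  w <- b[, 2L] - b[, 1L]
  if (region$strand == "+") {
    tx_starts <- cumsum(c(0L, w))[seq_along(w)]
    unname(tx_starts[idx] + (g_pos - b[idx, 1L]))
  } else {
    w_rev <- rev(w)
    tx_starts_rev <- cumsum(c(0L, w_rev))[seq_along(w_rev)]
    idx_rev <- nrow(b) + 1L - idx
    unname(tx_starts_rev[idx_rev] + (b[idx, 2L] - 1L - g_pos))
  }
}

#' Map a transcript interval to genomic blocks
#'
#' Projects a half-open transcript interval onto the genome. An interval that
#' crosses one or more exon junctions yields several genomic blocks; block
#' widths always sum to `t_end - t_start`.
#'
#' @param region A [spliced_region()].
#' @param t_start,t_end Transcript coordinates, `0 <= t_start < t_end <= length`.
#' @return Integer matrix (start, end) of genomic blocks in ascending
#'   genomic order.
#' @examples
#' r <- spliced_region("t", "g", "G", "chr1", "+", rbind(c(100, 150), c(200, 260)))
#' map_interval_to_genome(r, 48, 53) # rows (148,150) and (200,203)
#' @export
map_interval_to_genome <- function(region, t_start, t_end) {
  stopifnot(inherits(region, "spliced_region"))
  t_start <- as.integer(t_start); t_end <- as.integer(t_end)
  if (is.na(t_start) || is.na(t_end) || t_start < 0L || t_start >= t_end ||
      t_end > region$length)
    stop("invalid transcript interval [", t_start, ", ", t_end,
         ") for region of length ", region$length)
  w <- block_widths(region)
  n <- length(w)
  # transcript offset of each block, in transcript order
  ord <- if (region$strand == "+") seq_len(n) else rev(seq_len(n))
  tx_off <- cumsum(c(0L, w[ord]))[seq_len(n)]
  out <- vector("list", n)
  for (k in seq_len(n)) {
    i <- ord[k]
    lo <- max(t_start, tx_off[k]); hi <- min(t_end, tx_off[k] + w[i])
    if (lo >= hi) next
    if (region$strand == "+") {
      gs <- region$blocks[i, 1L] + (lo - tx_off[k])
      out[[k]] <- c(gs, gs + (hi - lo))
    } else {
      ge <- region$blocks[i, 2L] - (lo - tx_off[k])
      out[[k]] <- c(ge - (hi - lo), ge)
    }
  }
  m <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  m <- m[order(m[, 1L]), , drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- c("start", "end")
  m
}

# minimum gap between a block matrix and a single (start,end) span
min_gap_blocks <- function(blocks, start, end) {
  g <- pmax(0L, pmax(blocks[, 1L], start) - pmin(blocks[, 2L], end))
  min(g)
}
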