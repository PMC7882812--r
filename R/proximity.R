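#' Proximity-scan configuration
#'
#' @param max_distance_nt Pair-distance threshold in nucleotides, strict
#'   less-than (a pair at exactly this distance is excluded); default 20.
#' @param coordinate_space `"genomic"` (default) or `"spliced"`. In genomic
#'   mode the distance is the minimum gap between any QRE genomic block and
#'   the site interval; in spliced mode both features are projected into the
#'   transcript coordinate system of the UTR (sites outside the UTR's exonic
#'   blocks are skipped with a message). Within a single UTR exon the two
#'   measures coincide.
#' @return List of class `proximity_config`.
#' @export
proximity_config <- function(max_distance_nt = 20L,
                             coordinate_space = c("genomic", "spliced")) {
  if (max_distance_nt < 0L) stop("max_distance_nt must be >= 0")
  coordinate_space <- match.arg(coordinate_space)
  structure(list(max_distance_nt = as.integer(max_distance_nt),
                 coordinate_space = coordinate_space),
            class = "proximity_config")
}

#' Find QRE / miRNA-site pairs within the proximity threshold
#'
#' Pairs a validated QRE with a filtered miRNA target site when both are
#' annotated to the same gene's 3'UTR territory, lie on the same contig, and
#' their distance is strictly below the threshold. Overlap counts as
#' distance 0.
#'
#' @param validated Validated QRE data.frame from [validate_qres()].
#' @param sites Filtered site data.frame from [filter_sites()].
#' @param cfg A [proximity_config()].
#' @param utrs Named list of `utr3` objects (keyed by transcript id);
#'   required for `coordinate_space = "spliced"`.
#' @return data.frame, one row per proximal pair: gene/transcript ids, QRE
#'   transcript span and blocks, miRNA id, site interval, score,
#'   `distance_nt` and the QRE's `replicate_support`.
#' @export
find_proximal_pairs <- function(validated, sites, cfg = proximity_config(),
                                utrs = NULL) {
  if (is.null(validated) || is.null(sites)) stop("validated hits and sites required")
  empty <- data.frame(gene_symbol = character(), transcript_id = character(),
                      contig = character(), qre_t_start = integer(),
                      qre_blocks = character(), mirna_id = character(),
                      site_start = integer(), site_end = integer(),
                      mirsvr_score = numeric(), distance_nt = integer(),
                      replicate_support = integer(), stringsAsFactors = FALSE)
  if (nrow(validated) == 0L || nrow(sites) == 0L) return(empty)
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(validated))) {
    b <- validated$genomic_blocks[[i]]
    cand <- which(sites$gene_symbol == validated$gene_symbol[i] &
                    sites$contig == validated$contig[i])
    for (j in cand) {
      if (cfg$coordinate_space == "genomic") {
        d <- min_gap_blocks(b, sites$start[j], sites$end[j])
      } else {
        utr <- utrs[[validated$transcript_id[i]]]
        if (is.null(utr)) stop("spliced mode needs the utr3 for transcript ",
                               validated$transcript_id[i])
        ts <- site_to_transcript_span(utr$region, sites$start[j], sites$end[j])
        if (is.null(ts)) {
          message("site ", sites$mirna_id[j], " @", sites$start[j],
                  " lies outside the 3'UTR exonic blocks of ",
                  validated$transcript_id[i], "; pair skipped in spliced mode")
          next
        }
        d <- max(0L, max(validated$t_start[i], ts[1L]) -
                   min(validated$t_end[i], ts[2L]))
      }
      if (d < cfg$max_distance_nt) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          gene_symbol = validated$gene_symbol[i],
          transcript_id = validated$transcript_id[i],
          contig = validated$contig[i],
          qre_t_start = validated$t_start[i],
          qre_blocks = validated$blocks_str[i],
          mirna_id = sites$mirna_id[j],
          site_start = sites$start[j], site_end = sites$end[j],
          mirsvr_score = sites$mirsvr_score[j],
          distance_nt = as.integer(d),
          replicate_support = validated$replicate_support[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_symbol, out$qre_t_start, out$mirna_id, out$site_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# project a genomic span onto transcript coordinates; NULL if any base falls
# outside the region's exonic blocks
site_to_transcript_span <- function(region, g_start, g_end) {
  covered <- all(vapply(seq.int(g_start, g_end - 1L), function(p)
    any(region$blocks[, 1L] <= p & p < region$blocks[, 2L]), logical(1L)))
  if (!covered) return(NULL)
  tp <- map_from_genome(region, seq.int(g_start, g_end - 1L))
  c(min(tp), max(tp) + 1L)
}

#' Per-gene summary of proximal pairs
#'
#' @param pairs data.frame from [find_proximal_pairs()].
#' @return One row per gene with >= 1 pair, gene symbol ascending:
#'   `gene_symbol`, `n_pairs`, `best_distance_nt`, `n_mirnas`,
#'   `max_replicate_support`.
#' @export
summarize_genes <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(data.frame(gene_symbol = character(), n_pairs = integer(),
                      best_distance_nt = integer(), n_mirnas = integer(),
                      max_replicate_support = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(pairs, pairs$gene_symbol), function(g) {
    data.frame(gene_symbol = g$gene_symbol[1L],
               n_pairs = nrow(g),
               best_distance_nt = min(g$distance_nt),
               n_mirnas = length(unique(g$mirna_id)),
               max_replicate_support = max(g$replicate_support),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write proximal QREs and sites as a BED track
#'
#' Name fields encode the pairing (`QRE|gene|pairIdx` / `site|miRNA|pairIdx`)
#' so pairs can be matched up in a genome browser.
#'
#' @param pairs data.frame from [find_proximal_pairs()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_pairs_bed <- function(pairs, path) {
  lines <- character(0)
  for (i in seq_len(nrow(pairs))) {
    for (span in strsplit(pairs$qre_blocks[i], ",", fixed = TRUE)[[1L]]) {
      se <- as.integer(strsplit(span, "-", fixed = TRUE)[[1L]])
      lines <- c(lines, sprintf("%s\t%d\t%d\tQRE|%s|pair%d\t0\t.",
                                pairs$contig[i], se[1L], se[2L],
                                pairs$gene_symbol[i], i))
    }
    lines <- c(lines, sprintf("%s\t%d\t%d\tsite|%s|pair%d\t0\t.",
                              pairs$contig[i], pairs$site_start[i],
                              pairs$site_end[i], pairs$mirna_id[i], i))
  }
  writeLines(lines, path)
  invisible(path)
}
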