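#' QRE motif configuration
#'
#' The quaking response element is bipartite: a core `ACUAA` pentamer,
#' optionally followed within a short gap by a `UAAY` half-site (Y = C or U).
#' The downstream validation/proximity pipeline keys on the core alone; the
#' half-site is carried as annotation.
#'
#' @param core Core motif, RNA alphabet, default `"ACUAA"`.
#' @param half_site_pattern Half-site with IUPAC degeneracy, default `"UAAY"`.
#' @param half_site_max_gap Maximum gap (nt) between core end and half-site
#'   start searched by [annotate_half_site()], default 20.
#' @return List of class `qre_config`.
#' @export
qre_config <- function(core = "ACUAA", half_site_pattern = "UAAY",
                       half_site_max_gap = 20L) {
  if (!is.character(core) || length(core) != 1L || !nzchar(core))
    stop("core motif must be a non-empty string")
  if (grepl("[^ACGU]", core)) stop("core motif alphabet is {A,C,G,U}")
  if (half_site_max_gap < 0L) stop("half_site_max_gap must be >= 0")
  structure(list(core = core, half_site_pattern = half_site_pattern,
                 half_site_max_gap = as.integer(half_site_max_gap)),
            class = "qre_config")
}

#' Scan an RNA sequence for all core-motif occurrences
#'
#' Reports every occurrence, including overlapping ones, in ascending order.
#' `N` never matches.
#'
#' @param seq RNA string over `{A,C,G,U,N}`.
#' @param core Core motif (exact match, no degeneracy).
#' @return Integer vector of 0-based start positions.
#' @examples
#' scan_core_motif("ACUAACUAA", "ACUAA") # 0 4
#' @export
scan_core_motif <- function(seq, core = "ACUAA") {
  if (!nzchar(core)) stop("empty core motif")
  if (is.na(seq) || nchar(seq) < nchar(core)) return(integer(0))
  # zero-width lookahead so overlapping occurrences are all reported
  m <- gregexpr(paste0("(?=", core, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Find the nearest half-site downstream of a core hit
#'
#' Searches for the first match of the degenerate half-site pattern starting
#' within `[core_end, core_end + half_site_max_gap]` (transcript
#' coordinates).
#'
#' @param seq RNA string.
#' @param core_end 0-based position just past the core occurrence.
#' @param cfg A [qre_config()].
#' @return 0-based start of the half-site, or `NA_integer_` if none.
#' @export
annotate_half_site <- function(seq, core_end, cfg = qre_config()) {
  if (core_end < 0L || core_end > nchar(seq)) stop("core_end out of range")
  pat <- iupac_to_regex(cfg$half_site_pattern)
  pat_len <- nchar(cfg$half_site_pattern)
  last_start <- min(core_end + cfg$half_site_max_gap, nchar(seq) - pat_len)
  if (last_start < core_end) return(NA_integer_)
  window <- substr(seq, core_end + 1L, last_start + pat_len)
  m <- regexpr(pat, window, perl = TRUE)
  if (m == -1L) return(NA_integer_)
  core_end + as.integer(m) - 1L
}

# minimal IUPAC RNA degeneracy expansion for half-site patterns
iupac_to_regex <- function(pat) {
  map <- c(A = "A", C = "C", G = "G", U = "U",
           R = "[AG]", Y = "[CU]", S = "[CG]", W = "[AU]",
           K = "[GU]", M = "[AC]", B = "[CGU]", D = "[AGU]",
           H = "[ACU]", V = "[ACG]", N = "[ACGU]")
  chars <- strsplit(pat, "")[[1L]]
  bad <- !chars %in% names(map)
  if (any(bad)) stop("unsupported pattern symbol(s): ", paste(chars[bad], collapse = ""))
  paste(map[chars], collapse = "")
}

#' Scan a 3'UTR for QRE motifs
#'
#' One hit per core occurrence in the spliced RNA, with genomic blocks from
#' [map_interval_to_genome()] (a hit crossing an exon junction yields more
#' than one block and `spans_junction = TRUE`) and the half-site annotated.
#'
#' @param utr A `utr3` object from [build_utr3()].
#' @param cfg A [qre_config()].
#' @return data.frame with one row per hit: `transcript_id`, `gene_id`,
#'   `gene_symbol`, `contig`, `strand`, `t_start`, `t_end`, `core_seq`,
#'   `spans_junction`, `half_site_t_start`, `blocks_str`
#'   (`start-end` pairs comma-joined, ascending genomic order) and a
#'   `genomic_blocks` list column of integer matrices.
#' @export
scan_utr_qres <- function(utr, cfg = qre_config()) {
  stopifnot(inherits(utr, "utr3"))
  region <- utr$region
  starts <- scan_core_motif(utr$rna_sequence, cfg$core)
  k <- nchar(cfg$core)
  n <- length(starts)
  blocks <- vector("list", n)
  half <- integer(n)
  for (i in seq_len(n)) {
    blocks[[i]] <- map_interval_to_genome(region, starts[i], starts[i] + k)
    half[i] <- annotate_half_site(utr$rna_sequence, starts[i] + k, cfg)
  }
  out <- data.frame(
    transcript_id = rep(region$transcript_id, n),
    gene_id = rep(region$gene_id, n),
    gene_symbol = rep(region$gene_symbol, n),
    contig = rep(region$contig, n),
    strand = rep(region$strand, n),
    t_start = starts,
    t_end = starts + k,
    core_seq = if (n) substring(utr$rna_sequence, starts + 1L, starts + k) else character(0),
    spans_junction = vapply(blocks, nrow, integer(1L)) > 1L,
    half_site_t_start = half,
    blocks_str = vapply(blocks, format_blocks, character(1L)),
    stringsAsFactors = FALSE)
  out$genomic_blocks <- blocks
  out
}

format_blocks <- function(m) {
  paste(sprintf("%d-%d", m[, 1L], m[, 2L]), collapse = ",")
}

#' Count QRE core occurrences in a 3'UTR
#' @inheritParams scan_utr_qres
#' @return Integer count (all occurrences, overlaps included).
#' @export
count_qres <- function(utr, cfg = qre_config()) {
  nrow(scan_utr_qres(utr, cfg))
}

#' Scan a set of UTRs and bind the hits
#' @param utrs List of `utr3` objects.
#' @param cfg A [qre_config()].
#' @return Combined hit data.frame (see [scan_utr_qres()]).
#' @export
scan_all_qres <- function(utrs, cfg = qre_config()) {
  hits <- lapply(utrs, scan_utr_qres, cfg = cfg)
  do.call(rbind, c(hits, list(make.row.names = FALSE)))
}
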