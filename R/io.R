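#' Load a genome FASTA as a named character vector
#'
#' Reads every record of a FASTA file and returns its uppercased sequence
#' keyed by contig identifier (the first whitespace-delimited token of the
#' header).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per contig.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop("duplicate contig name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- nm
  out
}

#' Load transcript models from a GTF file
#'
#' Groups `exon`, `CDS` and `three_prime_utr` features by `transcript_id`.
#' GTF's 1-based closed spans are converted to the internal 0-based half-open
#' convention on entry; exons are sorted by genomic start.
#'
#' @param path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes on every feature row.
#' @return Named list of transcript models. Each model is a list with
#'   `transcript_id`, `gene_id`, `gene_symbol`, `contig`, `strand`, and
#'   integer block matrices `exons`, `cds`, `utr3` (the latter two possibly
#'   `NULL`).
#' @export
load_transcripts <- function(path) {
  if (!file.exists(path)) stop("GTF not found: ", path)
  gr <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  gr <- gr[gr$type %in% c("exon", "CDS", "three_prime_utr"), , drop = FALSE]
  if (nrow(gr) == 0L) stop("GTF contains no exon/CDS/three_prime_utr features: ", path)
  if (is.null(gr$transcript_id))
    stop("feature without transcript_id attribute in ", path)
  tid <- as.character(gr$transcript_id)
  if (anyNA(tid) || any(!nzchar(tid)))
    stop("feature without transcript_id attribute in ", path)
  gid <- as.character(gr$gene_id)
  sym <- if ("gene_name" %in% colnames(gr)) as.character(gr$gene_name) else gid
  sym[is.na(sym)] <- gid[is.na(sym)]
  df <- data.frame(
    transcript_id = tid, gene_id = gid, gene_symbol = sym,
    contig = as.character(gr$seqnames),
    strand = as.character(gr$strand),
    start = gr$start - 1L,   # 1-based closed -> 0-based half-open
    end = gr$end,
    type = as.character(gr$type),
    stringsAsFactors = FALSE)
  lapply(split(df, df$transcript_id), function(d) {
    if (length(unique(d$strand)) != 1L || any(!d$strand %in% c("+", "-")))
      stop("mixed or missing strand within transcript ", d$transcript_id[1L])
    if (length(unique(d$contig)) != 1L)
      stop("multiple contigs within transcript ", d$transcript_id[1L])
    pick <- function(ty) {
      b <- d[d$type == ty, c("start", "end"), drop = FALSE]
      if (nrow(b) == 0L) return(NULL)
      b <- as.matrix(b[order(b$start), , drop = FALSE])
      storage.mode(b) <- "integer"
      rownames(b) <- NULL
      b
    }
    list(transcript_id = d$transcript_id[1L], gene_id = d$gene_id[1L],
         gene_symbol = d$gene_symbol[1L], contig = d$contig[1L],
         strand = d$strand[1L],
         exons = pick("exon"), cds = pick("CDS"), utr3 = pick("three_prime_utr"))
  })
}

#' Load an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand, signalValue,
#' pValue (-log10), qValue (-log10), summit offset. BED coordinates are
#' already 0-based half-open and are kept unchanged.
#'
#' @param path Path to a 10-column narrowPeak file.
#' @param replicate_id Identifier attached to every peak (e.g. `"rep1"`).
#' @return data.frame with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand`, `signal_value`, `p_value_log`, `q_value_log`,
#'   `summit_offset`, `replicate_id`.
#' @export
load_peaks <- function(path, replicate_id) {
  if (!is.character(replicate_id) || !nzchar(replicate_id))
    stop("replicate_id must be a non-empty string")
  if (!file.exists(path)) stop("narrowPeak not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L)   # no peaks called
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      signal_value = numeric(), p_value_log = numeric(),
                      q_value_log = numeric(), summit_offset = integer(),
                      replicate_id = character(), stringsAsFactors = FALSE))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (ncol(raw) != 10L)
    stop("narrowPeak requires 10 columns, got ", ncol(raw), ": ", path)
  pk <- data.frame(
    contig = raw[[1L]],
    start = as.integer(raw[[2L]]),
    end = as.integer(raw[[3L]]),
    name = raw[[4L]],
    score = as.numeric(raw[[5L]]),
    strand = raw[[6L]],
    signal_value = as.numeric(raw[[7L]]),
    p_value_log = as.numeric(raw[[8L]]),
    q_value_log = as.numeric(raw[[9L]]),
    summit_offset = as.integer(raw[[10L]]),
    replicate_id = replicate_id,
    stringsAsFactors = FALSE)
  if (anyNA(pk$start) || anyNA(pk$end)) stop("non-numeric coordinates in ", path)
  if (any(pk$start >= pk$end)) stop("peak with start >= end in ", path)
  pk
}

#' Load a miRNA target-site table
#'
#' Tab-separated with a header naming at least `mirna_id`, `contig`, `start`,
#' `end`, `strand`, `gene`, `mirsvr_score`. Coordinates are 0-based half-open.
#' The mirSVR-style score may be negative (more negative = stronger predicted
#' repression).
#'
#' @param path Path to the TSV.
#' @return data.frame of sites with validated intervals and numeric scores.
#' @export
load_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  tb <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  need <- c("mirna_id", "contig", "start", "end", "strand", "gene", "mirsvr_score")
  miss <- setdiff(need, colnames(tb))
  if (length(miss)) stop("site table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tb) == 0L) return(empty_site_frame())
  st <- suppressWarnings(as.integer(tb$start))
  en <- suppressWarnings(as.integer(tb$end))
  sc <- suppressWarnings(as.numeric(tb$mirsvr_score))
  if (anyNA(st) || anyNA(en)) stop("non-numeric start/end in site table: ", path)
  if (anyNA(sc)) stop("non-numeric mirsvr_score in site table: ", path)
  if (any(st < 0L) || any(st >= en)) stop("invalid interval(s) in site table: ", path)
  data.frame(mirna_id = tb$mirna_id, gene_symbol = tb$gene,
             transcript_id = if ("transcript_id" %in% colnames(tb)) tb$transcript_id else NA_character_,
             contig = tb$contig, start = st, end = en, strand = tb$strand,
             mirsvr_score = sc, stringsAsFactors = FALSE)
}

empty_site_frame <- function() {
  data.frame(mirna_id = character(), gene_symbol = character(),
             transcript_id = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             mirsvr_score = numeric(), stringsAsFactors = FALSE)
}

#' Load an expression table
#'
#' Tab-separated, first column the feature identifier, remaining columns one
#' numeric value per sample/condition. Values must be non-negative; duplicate
#' feature keys are rejected.
#'
#' @param path Path to the TSV.
#' @return data.frame with rownames = feature ids and numeric sample columns.
#' @export
load_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tb <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#")
  if (ncol(tb) < 2L) stop("expression table needs an id column plus >= 1 sample column")
  ids <- as.character(tb[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature key(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.data.frame(lapply(tb[-1L], as.numeric), check.names = FALSE)
  if (any(vapply(vals, anyNA, logical(1L)))) stop("non-numeric expression value in ", path)
  if (any(as.matrix(vals) < 0)) stop("negative expression value in ", path)
  rownames(vals) <- ids
  vals
}

#' Write a TSV report with provenance metadata
#'
#' Emits '#'-prefixed metadata lines (tool version plus any parameters
#' supplied) followed by a header line and tab-separated rows, so every
#' report is self-describing.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param params Named list echoed verbatim as `# key = value` lines.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# qrescan %s", as.character(utils::packageVersion("qrescan"))), con)
  for (k in names(params))
    writeLines(sprintf("# %s = %s", k, paste(format(params[[k]]), collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a report written by [write_report_tsv()]
#' @param path Path to the TSV.
#' @return data.frame (metadata lines skipped).
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
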