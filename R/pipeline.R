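#' Run configuration for the full pipeline
#'
#' Bundles the input paths and the per-stage configurations. Every
#' threshold is echoed verbatim into the run manifest.
#'
#' @param genome_path,gtf_path,sites_path,mirna_expr_path Input files.
#' @param peak_paths Named character vector: replicate id -> narrowPeak path.
#' @param out_dir Output directory for the report bundle.
#' @param qre_cfg,filter_cfg,prox_cfg Stage configurations.
#' @param min_replicates Minimum eCLIP replicate support, default 1.
#' @return List of class `run_config`.
#' @export
run_config <- function(genome_path, gtf_path, sites_path, mirna_expr_path,
                       peak_paths, out_dir,
                       qre_cfg = qre_config(),
                       filter_cfg = site_filter_config(),
                       prox_cfg = proximity_config(),
                       min_replicates = 1L) {
  if (is.null(names(peak_paths)) || any(!nzchar(names(peak_paths))))
    stop("peak_paths must be named by replicate id")
  structure(list(genome_path = genome_path, gtf_path = gtf_path,
                 sites_path = sites_path, mirna_expr_path = mirna_expr_path,
                 peak_paths = peak_paths, out_dir = out_dir,
                 qre_cfg = qre_cfg, filter_cfg = filter_cfg,
                 prox_cfg = prox_cfg, min_replicates = as.integer(min_replicates)),
            class = "run_config")
}

#' Run the motif/validation/proximity pipeline
#'
#' Stages, in order: 3'UTR extraction -> QRE scan -> miRNA-site filtering ->
#' eCLIP validation -> proximity scan -> per-gene summary. Writes the pair
#' report, gene summary, validated-QRE table, BED track and a JSON manifest
#' (parameters echoed verbatim, per-stage feature counts) into `out_dir`.
#'
#' @param cfg A [run_config()].
#' @return Invisible list with `utrs`, `hits`, `filtered_sites`,
#'   `validated`, `pairs`, `gene_summary`, `counts` and `manifest_path`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
    res
  }
  genome <- stage("load_genome", load_genome(cfg$genome_path))
  transcripts <- stage("load_transcripts", load_transcripts(cfg$gtf_path))
  utrs <- stage("extract_utr", build_all_utr3(transcripts, genome))
  hits <- stage("scan_qre", scan_all_qres(utrs, cfg$qre_cfg))
  if (is.null(hits)) hits <- scan_utr_qres_empty()
  sites <- stage("load_sites", load_site_table(cfg$sites_path))
  mirna_expr <- stage("load_mirna_expr", load_expression_table(cfg$mirna_expr_path))
  filtered <- stage("filter_mirna", filter_sites(sites, mirna_expr, cfg$filter_cfg))
  peaks <- stage("load_peaks", mapply(load_peaks, cfg$peak_paths,
                                      names(cfg$peak_paths), SIMPLIFY = FALSE))
  validated <- stage("validate_eclip",
                     validate_qres(hits, peaks, cfg$min_replicates))
  pairs <- stage("scan_proximity",
                 find_proximal_pairs(validated, filtered, cfg$prox_cfg, utrs))
  gene_summary <- stage("summarize", summarize_genes(pairs))

  counts <- c(transcripts = length(transcripts), utrs = length(utrs),
              qre_hits = nrow(hits), sites_in = nrow(sites),
              sites_filtered = nrow(filtered), validated_qres = nrow(validated),
              proximal_pairs = nrow(pairs), proximal_genes = nrow(gene_summary))
  message(paste(sprintf("%s=%d", names(counts), counts), collapse = " "))

  params <- list(core = cfg$qre_cfg$core,
                 half_site_pattern = cfg$qre_cfg$half_site_pattern,
                 half_site_max_gap = cfg$qre_cfg$half_site_max_gap,
                 expression_top_fraction = cfg$filter_cfg$expression_top_fraction,
                 mirsvr_cutoff = cfg$filter_cfg$mirsvr_cutoff,
                 max_distance_nt = cfg$prox_cfg$max_distance_nt,
                 coordinate_space = cfg$prox_cfg$coordinate_space,
                 min_replicates = cfg$min_replicates)
  drop_cols <- function(df) df[, setdiff(colnames(df), "genomic_blocks"), drop = FALSE]
  write_report_tsv(drop_cols(validated),
                   file.path(cfg$out_dir, "validated_qres.tsv"), params)
  write_report_tsv(pairs, file.path(cfg$out_dir, "proximal_pairs.tsv"), params)
  write_report_tsv(gene_summary, file.path(cfg$out_dir, "gene_summary.tsv"), params)
  write_pairs_bed(pairs, file.path(cfg$out_dir, "proximal_pairs.bed"))
  manifest <- list(
    tool = "qrescan",
    version = as.character(utils::packageVersion("qrescan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = params,
    inputs = lapply(c(genome = cfg$genome_path, gtf = cfg$gtf_path,
                      sites = cfg$sites_path, mirna_expr = cfg$mirna_expr_path,
                      cfg$peak_paths),
                    function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    stage_counts = as.list(counts))
  manifest_path <- file.path(cfg$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(utrs = utrs, hits = hits, filtered_sites = filtered,
                 validated = validated, pairs = pairs,
                 gene_summary = gene_summary, counts = counts,
                 manifest_path = manifest_path))
}

# zero-row hit frame with the scan_utr_qres schema
scan_utr_qres_empty <- function() {
  out <- data.frame(transcript_id = character(), gene_id = character(),
                    gene_symbol = character(), contig = character(),
                    strand = character(), t_start = integer(), t_end = integer(),
                    core_seq = character(), spans_junction = logical(),
                    half_site_t_start = integer(), blocks_str = character(),
                    stringsAsFactors = FALSE)
  out$genomic_blocks <- list()
  out
}
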