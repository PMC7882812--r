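#' miRNA target-site filter configuration
#'
#' Mirrors the two published filters: keep sites of miRNAs whose expression
#' lies in the top fraction of the expression table (default top 50%, ties at
#' the threshold included) and whose mirSVR-style score is strictly below the
#' cutoff (default -1; a score of exactly -1 is dropped).
#'
#' @param expression_top_fraction Fraction in (0, 1], default 0.5.
#' @param mirsvr_cutoff Score cutoff, strict less-than, default -1.
#' @return List of class `site_filter_config`.
#' @export
site_filter_config <- function(expression_top_fraction = 0.5, mirsvr_cutoff = -1.0) {
  if (!(expression_top_fraction > 0 && expression_top_fraction <= 1))
    stop("expression_top_fraction must lie in (0, 1]")
  structure(list(expression_top_fraction = expression_top_fraction,
                 mirsvr_cutoff = mirsvr_cutoff),
            class = "site_filter_config")
}

#' Filter miRNA target sites by expression and targeting score
#'
#' The expression reference population is every miRNA in the expression
#' table (not only those with sites); a miRNA passes when its value is >=
#' the `1 - top_fraction` quantile of all table values, so with all-equal
#' values everything passes. Multiple sample columns are averaged per miRNA
#' before ranking. Sites of miRNAs absent from the table fail the expression
#' filter (counted, not an error). The score filter is a strict `<`.
#'
#' @param sites data.frame from [load_site_table()].
#' @param mirna_expr Expression data.frame from [load_expression_table()]
#'   keyed by miRNA id.
#' @param cfg A [site_filter_config()].
#' @return The input data.frame with logical columns `expressed_rank_pass`
#'   and `score_pass` appended, restricted to rows passing both; the full
#'   audited table (all rows, both flags) is attached as
#'   `attr(, "audit")`.
#' @export
filter_sites <- function(sites, mirna_expr, cfg = site_filter_config()) {
  if (nrow(mirna_expr) == 0L) stop("empty miRNA expression table")
  expr_val <- rowMeans(as.matrix(mirna_expr))
  thr <- stats::quantile(expr_val, probs = 1 - cfg$expression_top_fraction,
                         names = FALSE, type = 7)
  site_val <- expr_val[sites$mirna_id]
  missing_n <- sum(is.na(site_val))
  if (missing_n > 0L)
    message(missing_n, " site(s) reference miRNAs absent from the expression table; ",
            "treated as not expressed")
  audit <- sites
  audit$expressed_rank_pass <- !is.na(site_val) & site_val >= thr
  audit$score_pass <- sites$mirsvr_score < cfg$mirsvr_cutoff
  out <- audit[audit$expressed_rank_pass & audit$score_pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Single-linkage clustering of target sites
#'
#' Two sites join one cluster when the gap between their intervals is at
#' most `max_gap` (0 = overlapping or book-ended). Clustering is per contig.
#'
#' @param sites data.frame with `contig`, `start`, `end` columns.
#' @param max_gap Maximum joining gap in nt, default 0.
#' @return data.frame with one row per cluster: `contig`, `start`, `end`
#'   (spanning interval), `n_members`, `members` (comma-joined miRNA ids when
#'   present).
#' @export
cluster_sites <- function(sites, max_gap = 0L) {
  if (nrow(sites) == 0L)
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      n_members = integer(), members = character(),
                      stringsAsFactors = FALSE))
  res <- lapply(split(sites, sites$contig), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    # a new cluster opens when the gap to the running right edge exceeds max_gap
    run_end <- d$end[1L]
    cl <- integer(nrow(d)); cl[1L] <- 1L
    for (i in seq_len(nrow(d))[-1L]) {
      gap <- max(0L, d$start[i] - run_end)
      cl[i] <- if (gap > max_gap) cl[i - 1L] + 1L else cl[i - 1L]
      run_end <- if (gap > max_gap) d$end[i] else max(run_end, d$end[i])
    }
    do.call(rbind, lapply(split(d, cl), function(g) {
      data.frame(contig = g$contig[1L], start = min(g$start), end = max(g$end),
                 n_members = nrow(g),
                 members = if ("mirna_id" %in% colnames(g))
                   paste(g$mirna_id, collapse = ",") else "",
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
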