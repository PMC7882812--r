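#' Regulation-calling configuration
#'
#' @param lfc_threshold Absolute log2 fold-change threshold for a direction
#'   call, inclusive at the boundary; default 0.4 (the panel analyses use
#'   +/- 0.4 on the log2 scale).
#' @param min_support Datasets that must agree for a consensus direction;
#'   default 2 (of 3).
#' @param pseudocount Added to numerator and denominator before the log2
#'   ratio; default 1 (use 0 for intensity data that is never zero).
#' @return List of class `regulation_config`.
#' @export
regulation_config <- function(lfc_threshold = 0.4, min_support = 2L,
                              pseudocount = 1) {
  if (lfc_threshold < 0) stop("lfc_threshold must be >= 0")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  structure(list(lfc_threshold = lfc_threshold,
                 min_support = as.integer(min_support),
                 pseudocount = pseudocount),
            class = "regulation_config")
}

#' Detectable panel genes
#'
#' A panel gene is detectable when it has a strictly positive value in at
#' least one sample of the expression table. Panel genes absent from the
#' table are counted as not detectable (with a message), not an error.
#'
#' @param expr Expression data.frame from [load_expression_table()].
#' @param panel Character vector of gene identifiers.
#' @return Character vector: the detectable subset of `panel`, input order.
#' @export
detectable_genes <- function(expr, panel) {
  if (length(panel) == 0L) stop("empty gene panel")
  present <- panel %in% rownames(expr)
  if (any(!present))
    message(sum(!present), " panel gene(s) absent from the expression table")
  keep <- vapply(panel, function(g) {
    present[match(g, panel)] && any(as.numeric(expr[g, ]) > 0)
  }, logical(1L))
  panel[keep]
}

#' Pseudocounted log2 fold change
#'
#' `log2((numerator + pseudocount) / (denominator + pseudocount))`.
#' Antisymmetric in its two arguments for any shared pseudocount.
#'
#' @param numerator,denominator Non-negative expression values (vectorised).
#' @param pseudocount Non-negative; must be > 0 if both values can be 0.
#' @return log2 fold change(s).
#' @export
log2_fold_change <- function(numerator, denominator, pseudocount = 1) {
  if (any(numerator < 0) || any(denominator < 0))
    stop("expression values must be non-negative")
  if (pseudocount == 0 && any(numerator == 0 & denominator == 0))
    stop("both values zero with pseudocount 0: fold change undefined")
  log2((numerator + pseudocount) / (denominator + pseudocount))
}

#' Direction call from a log2 fold change
#'
#' `"Up"` when lfc >= threshold, `"Down"` when lfc <= -threshold (both
#' inclusive), else `"None"`. Vectorised.
#'
#' @param log2fc Finite numeric vector.
#' @param cfg A [regulation_config()].
#' @return Character vector over `{"Up", "Down", "None"}`.
#' @export
call_direction <- function(log2fc, cfg = regulation_config()) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  ifelse(log2fc >= cfg$lfc_threshold, "Up",
         ifelse(log2fc <= -cfg$lfc_threshold, "Down", "None"))
}

#' Consensus direction across datasets for one gene
#'
#' Direction-only rule: the consensus is the direction called in at least
#' `min_support` datasets; `conflict` is set whenever both directions have
#' at least one call; if both directions reach support (impossible with 3
#' datasets and support 2) or neither does, the consensus is `"None"`.
#' Calls of `"-"` or `"None"` count toward neither direction.
#'
#' @param calls data.frame with columns `dataset_id` and `call`
#'   (`{"Up","Down","None","-"}`) for a single gene.
#' @param cfg A [regulation_config()].
#' @return List with `consensus` (`"Up"`, `"Down"` or `"None"`), `n_up`,
#'   `n_down` and `conflict`.
#' @export
consensus_call <- function(calls, cfg = regulation_config()) {
  if (nrow(calls) == 0L) stop("at least one dataset call required")
  if (anyDuplicated(calls$dataset_id))
    stop("duplicate dataset_id: ",
         paste(unique(calls$dataset_id[duplicated(calls$dataset_id)]), collapse = ", "))
  if (cfg$min_support > nrow(calls))
    stop("min_support exceeds the number of datasets")
  n_up <- sum(calls$call == "Up")
  n_down <- sum(calls$call == "Down")
  up_ok <- n_up >= cfg$min_support
  down_ok <- n_down >= cfg$min_support
  consensus <- if (up_ok && !down_ok) "Up"
               else if (down_ok && !up_ok) "Down"
               else "None"
  list(consensus = consensus, n_up = n_up, n_down = n_down,
       conflict = n_up > 0L && n_down > 0L)
}

#' Consensus calls for a whole call matrix
#'
#' @param call_table Long data.frame with columns `gene`, `dataset_id`,
#'   `call` (one row per gene x dataset).
#' @param cfg A [regulation_config()].
#' @return data.frame, gene ascending: `gene`, `consensus`, `n_up`,
#'   `n_down`, `conflict`.
#' @export
consensus_table <- function(call_table, cfg = regulation_config()) {
  out <- do.call(rbind, lapply(split(call_table, call_table$gene), function(d) {
    cc <- consensus_call(d, cfg)
    data.frame(gene = d$gene[1L], consensus = cc$consensus, n_up = cc$n_up,
               n_down = cc$n_down, conflict = cc$conflict,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Patient-versus-sibling direction calls
#'
#' For each panel gene and each shared cell-state column, the log2 fold
#' change of patient over sibling expression and its threshold call.
#' Genes missing from either table are skipped with a message.
#'
#' @param patient_expr,sibling_expr Expression data.frames with matching
#'   condition columns (e.g. `monocyte`, `macrophage`).
#' @param panel Character vector of genes to compare.
#' @param cfg A [regulation_config()].
#' @return data.frame: `gene`, `condition`, `log2fc`, `call`.
#' @export
patient_comparison <- function(patient_expr, sibling_expr, panel,
                               cfg = regulation_config()) {
  conds <- intersect(colnames(patient_expr), colnames(sibling_expr))
  if (length(conds) == 0L) stop("no shared condition columns")
  keep <- panel %in% rownames(patient_expr) & panel %in% rownames(sibling_expr)
  if (any(!keep))
    message(sum(!keep), " panel gene(s) missing from patient or sibling table; skipped")
  genes <- panel[keep]
  out <- expand.grid(gene = genes, condition = conds,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$log2fc <- mapply(function(g, cn)
    log2_fold_change(patient_expr[g, cn], sibling_expr[g, cn], cfg$pseudocount),
    out$gene, out$condition)
  out$call <- call_direction(out$log2fc, cfg)
  out[order(out$gene, out$condition), , drop = FALSE]
}

#' Pearson correlation between two expression vectors
#'
#' Used for the regulator-versus-target association (e.g. QKI vs SEMA7A
#' across knockdown donors): Pearson r with a two-sided t-test p-value.
#'
#' @param x,y Numeric vectors, length >= 3, non-constant.
#' @return List with `r` and `p`.
#' @export
qki_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Join per-gene QRE counts with fold changes
#'
#' Inner join on gene, deterministic (gene ascending) order; the table
#' behind the count-versus-fold-change scatter.
#'
#' @param qre_counts Named integer vector or data.frame (`gene`,
#'   `qre_count`).
#' @param fc_table data.frame with columns `gene` and `log2fc`.
#' @return data.frame: `gene`, `qre_count`, `log2fc`.
#' @export
join_counts_fc <- function(qre_counts, fc_table) {
  if (!is.data.frame(qre_counts))
    qre_counts <- data.frame(gene = names(qre_counts),
                             qre_count = as.integer(qre_counts),
                             stringsAsFactors = FALSE)
  out <- merge(qre_counts, fc_table[, c("gene", "log2fc")], by = "gene")
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Packaged cross-dataset call matrix for the regulated-gene panel
#'
#' Loads the package's fixture of per-dataset direction calls (17 genes x 3
#' monocyte-to-macrophage differentiation datasets, significance flags kept
#' as metadata) used by the consensus worked example.
#'
#' @return Long data.frame: `gene`, `dataset_id`, `call`, `significant`.
#' @export
load_ngc_call_matrix <- function() {
  path <- system.file("extdata", "ngc_dataset_calls.tsv", package = "qrescan")
  tb <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  tb$significant <- as.logical(tb$significant)
  tb
}
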