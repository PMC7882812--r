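#' Cross-validate QRE hits against eCLIP peak replicates
#'
#' A hit is supported by a replicate when any of its genomic blocks overlaps
#' (>= 1 bp) any peak of that replicate on the same contig; peak strand is
#' ignored (narrowPeak strand is frequently '.'). `replicate_support` counts
#' supporting replicates; hits reaching `min_replicates` are returned, each
#' with its support value and per-replicate flags, so the stricter
#' "supported in both duplicates" view is a column, not a refit.
#'
#' @param hits QRE hit data.frame from [scan_utr_qres()]/[scan_all_qres()].
#' @param peaks_by_replicate Named list mapping replicate id to a peak
#'   data.frame from [load_peaks()].
#' @param min_replicates Minimum supporting replicates to keep a hit,
#'   default 1.
#' @return `hits` restricted to validated rows, with `replicate_support`,
#'   `supporting_peaks` (comma-joined peak names) and one logical
#'   `support_<replicate>` column per replicate.
#' @export
validate_qres <- function(hits, peaks_by_replicate, min_replicates = 1L) {
  if (length(peaks_by_replicate) == 0L) stop("at least one peak replicate required")
  if (is.null(names(peaks_by_replicate)) || any(!nzchar(names(peaks_by_replicate))))
    stop("peaks_by_replicate must be a named list (replicate ids)")
  if (min_replicates > length(peaks_by_replicate))
    stop("min_replicates (", min_replicates, ") exceeds replicates provided (",
         length(peaks_by_replicate), ")")
  n <- nrow(hits)
  rep_ids <- names(peaks_by_replicate)
  support <- matrix(FALSE, nrow = n, ncol = length(rep_ids),
                    dimnames = list(NULL, rep_ids))
  peak_names <- vector("list", n)
  for (r in rep_ids) {
    pk <- peaks_by_replicate[[r]]
    for (i in seq_len(n)) {
      b <- hits$genomic_blocks[[i]]
      same <- pk$contig == hits$contig[i]
      if (!any(same)) next
      ov <- rep(FALSE, sum(same))
      ps <- pk$start[same]; pe <- pk$end[same]
      for (j in seq_len(nrow(b)))
        ov <- ov | (ps < b[j, 2L] & b[j, 1L] < pe)
      if (any(ov)) {
        support[i, r] <- TRUE
        peak_names[[i]] <- c(peak_names[[i]], pk$name[same][ov])
      }
    }
  }
  out <- hits
  out$replicate_support <- as.integer(rowSums(support))
  out$supporting_peaks <- vapply(peak_names, function(x)
    paste(unique(x), collapse = ","), character(1L))
  for (r in rep_ids) out[[paste0("support_", r)]] <- support[, r]
  out <- out[out$replicate_support >= min_replicates, , drop = FALSE]
  rownames(out) <- NULL
  out
}
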