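#' Transcripts-per-million column scaling
#'
#' Rescales every sample (column) of a count matrix so that it sums to 10^6:
#' `TPM = 1e6 * x / sum(x)` per column. This is a pure library-size scaling
#' with no transcript-length correction; proportions within a column are
#' preserved exactly.
#'
#' @param m an [expression_matrix()] with `kind = "counts"`.
#' @return an [expression_matrix()] with `kind = "normalized"` whose columns
#'   each sum to 10^6.
#' @export
tpm_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$kind != "counts") {
    stop("tpm_normalize expects raw counts (kind = \"counts\")")
  }
  totals <- colSums(m$values)
  if (any(totals <= 0)) {
    bad <- m$sample_ids[totals <= 0]
    stop("all-zero column(s): ", paste(bad, collapse = ", "))
  }
  vals <- sweep(m$values, 2, totals, "/") * 1e6
  expression_matrix(vals, "normalized")
}

#' Half-of-means gene filter
#'
#' Computes two global thresholds from the matrix: the mean of all nonzero
#' entries and the mean of all entries. A gene is retained iff its own mean
#' expression strictly exceeds half of BOTH thresholds; ties at the boundary
#' are dropped. Intended for TPM-scale (or comparably scaled pre-normalized)
#' data; it is the only adjustment step applied to pre-normalized input.
#'
#' @param m an [expression_matrix()] on a TPM-like scale.
#' @return a list with elements `matrix` (the filtered [expression_matrix()])
#'   and `report` (class `filter_report`: kept/dropped ids and the two
#'   thresholds).
#' @export
filter_genes <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  v <- m$values
  nz <- v[v != 0]
  t_nonzero <- if (length(nz)) mean(nz) else 0
  t_overall <- mean(v)
  gene_means <- rowMeans(v)
  keep <- gene_means > 0.5 * t_nonzero & gene_means > 0.5 * t_overall
  if (!any(keep)) {
    stop("no genes survive the half-of-means filter; review input scaling")
  }
  report <- structure(
    list(kept = m$gene_ids[keep], dropped = m$gene_ids[!keep],
         threshold_nonzero_mean = t_nonzero, threshold_overall_mean = t_overall),
    class = "filter_report"
  )
  list(matrix = expression_matrix(v[keep, , drop = FALSE], m$kind),
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter_report> kept %d, dropped %d (nonzero mean %.4g, overall mean %.4g)\n",
    length(x$kept), length(x$dropped),
    x$threshold_nonzero_mean, x$threshold_overall_mean))
  invisible(x)
}

#' Write a filter report as TSV
#'
#' One row per input gene with its status; the two global thresholds are
#' recorded in `#`-prefixed header comments so the filter can be audited.
#'
#' @param report a `filter_report` from [filter_genes()].
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# threshold_nonzero_mean\t%.15g", report$threshold_nonzero_mean),
    sprintf("# threshold_overall_mean\t%.15g", report$threshold_overall_mean),
    "gene\tstatus"), con)
  df <- data.frame(
    gene = c(report$kept, report$dropped),
    status = rep(c("kept", "dropped"),
                 c(length(report$kept), length(report$dropped))))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Log2 transform: log2(x + 1)
#'
#' Maps every entry x to `log(x + 1)/log(2)`. The map is strictly increasing,
#' so within-column rank order is preserved.
#'
#' @param m an [expression_matrix()] with nonnegative entries.
#' @return an [expression_matrix()] with `kind = "normalized"`.
#' @export
log_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (any(m$values < 0)) stop("negative entries cannot be log-normalized")
  expression_matrix(log2(m$values + 1), "normalized")
}
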