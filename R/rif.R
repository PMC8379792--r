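#' Read a transcription-factor catalog
#'
#' Plain text, one identifier per line; blank lines and `#` comments ignored.
#'
#' @param path catalog file.
#' @return character vector of TF ids.
#' @export
read_tf_catalog <- function(path) {
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  ids <- unique(ids)
  if (!length(ids)) stop("TF catalog is empty")
  ids
}

# Pearson correlation between the rows of `a` and the rows of `b` over the
# sample columns `idx`. Zero-variance rows are mapped to r = 0 (a co-expression
# statement about a flat profile is undefined; 0 keeps the matrix usable) and
# their ids are returned so callers can warn.
row_correlations <- function(a, b, idx) {
  ta <- t(a[, idx, drop = FALSE])
  tb <- t(b[, idx, drop = FALSE])
  flat_a <- apply(ta, 2, stats::sd) == 0
  flat_b <- apply(tb, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(ta, tb))
  r[is.na(r)] <- 0
  list(r = r, flat = c(colnames(ta)[flat_a], colnames(tb)[flat_b]))
}

#' Assemble the per-condition correlation input for RIF scoring
#'
#' For each of the two conditions, computes the Pearson correlation between
#' every transcription factor and every differentially expressed (DE) gene
#' over that condition's samples, together with the DE genes' per-condition
#' mean expression, overall mean expression, and standardized differential
#' expression. DE genes are the non-`ns` rows of the classification that are
#' not themselves TFs. TFs listed in the catalog but absent from the matrix
#' are reported in the `missing_tfs` field, not silently dropped.
#'
#' @param m normalized [expression_matrix()].
#' @param de a `de_classification` from [classify_de()].
#' @param tfs character vector of TF ids (see [read_tf_catalog()]).
#' @param d a [condition_design()]; each condition needs >= 3 samples.
#' @return an object of class `rif_input`.
#' @export
build_rif_input <- function(m, de, tfs, d) {
  stopifnot(inherits(m, "expression_matrix"),
            inherits(de, "de_classification"),
            inherits(d, "condition_design"))
  missing_tfs <- setdiff(tfs, m$gene_ids)
  tf_ids <- intersect(m$gene_ids, tfs)
  if (!length(tf_ids)) stop("no catalog TF present in the expression matrix")
  de_ids <- de$gene[de$status != "ns" & !de$is_tf]
  de_ids <- intersect(de_ids, m$gene_ids)
  if (!length(de_ids)) stop("no differentially expressed genes to score against")
  ref_idx <- design_samples(m, d, d$reference)
  alt_idx <- design_samples(m, d, d$alternate)
  if (length(ref_idx) < 3 || length(alt_idx) < 3) {
    stop("each condition needs >= 3 samples for correlation estimates")
  }
  tf_mat <- m$values[tf_ids, , drop = FALSE]
  de_mat <- m$values[de_ids, , drop = FALSE]
  c_ref <- row_correlations(tf_mat, de_mat, ref_idx)
  c_alt <- row_correlations(tf_mat, de_mat, alt_idx)
  flat <- unique(c(c_ref$flat, c_alt$flat))
  if (length(flat)) {
    warning("zero-variance profiles within a condition (correlations set to 0): ",
            paste(flat, collapse = ", "))
  }
  structure(list(
    r_ref = c_ref$r,                 # TF x DE, reference-condition samples
    r_alt = c_alt$r,
    e_ref = rowMeans(de_mat[, ref_idx, drop = FALSE]),
    e_alt = rowMeans(de_mat[, alt_idx, drop = FALSE]),
    a = rowMeans(de_mat),            # overall DE-gene abundance
    diff = stats::setNames(de$diff, de$gene)[de_ids],
    tf_avgexpr = rowMeans(tf_mat),
    tf_ids = tf_ids,
    de_ids = de_ids,
    reference = d$reference,
    alternate = d$alternate,
    missing_tfs = missing_tfs
  ), class = "rif_input")
}

#' Regulatory Impact Factor scores
#'
#' For TF i over the n DE genes j, with r^(1), r^(2) the per-condition
#' TF-to-DE-gene correlations and e^(1), e^(2) the DE genes' condition means:
#'
#' * `RIF1_i = (1/n) * sum_j PIF_j * (r_ij^(1) - r_ij^(2))^2`, where the
#'   phenotype impact factor `PIF_j = a_j * diff_j` weights each DE gene by
#'   its overall abundance times its signed standardized differential
#'   expression — RIF1 favours TFs whose wiring to abundant, strongly DE
#'   genes changes most between conditions.
#' * `RIF2_i = (1/n) * sum_j [(e_j^(1) r_ij^(1))^2 - (e_j^(2) r_ij^(2))^2]` —
#'   RIF2 measures the change in the TF's ability to predict DE-gene
#'   abundance.
#'
#' Both raw vectors are z-standardized across TFs (n-1 standard deviation)
#' into the reported RIF1/RIF2 columns; a TF is flagged significant on a
#' score when its absolute standardized value exceeds 1.96.
#'
#' @param input a `rif_input` from [build_rif_input()].
#' @param sig_cutoff threshold on the standardized scores; default 1.96.
#' @return a data frame of class `rif_table` with columns `TF`, `avgexpr`,
#'   `RIF1`, `RIF2`, `rif1_raw`, `rif2_raw`, `sig1`, `sig2`.
#' @export
rif_scores <- function(input, sig_cutoff = 1.96) {
  stopifnot(inherits(input, "rif_input"))
  n_tf <- length(input$tf_ids)
  if (n_tf < 2) stop("standardization needs >= 2 TFs")
  pif <- input$a * input$diff
  dw2 <- (input$r_ref - input$r_alt)^2          # squared differential wiring
  rif1_raw <- as.vector(dw2 %*% pif) / length(input$de_ids)
  pred <- sweep(input$r_ref, 2, input$e_ref, "*")^2 -
          sweep(input$r_alt, 2, input$e_alt, "*")^2
  rif2_raw <- rowMeans(pred)
  zstd <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  if (stats::sd(rif1_raw) == 0 || stats::sd(rif2_raw) == 0) {
    warning("zero variance of raw RIF scores; standardized scores set to 0")
  }
  rif1 <- zstd(rif1_raw)
  rif2 <- zstd(rif2_raw)
  out <- data.frame(
    TF = input$tf_ids,
    avgexpr = unname(input$tf_avgexpr),
    RIF1 = rif1,
    RIF2 = rif2,
    rif1_raw = rif1_raw,
    rif2_raw = rif2_raw,
    sig1 = abs(rif1) > sig_cutoff,
    sig2 = abs(rif2) > sig_cutoff,
    stringsAsFactors = FALSE
  )
  attr(out, "sig_cutoff") <- sig_cutoff
  class(out) <- c("rif_table", "data.frame")
  out
}

#' Transcription factors called significant by the RIF criterion
#'
#' A TF is significant if `|RIF1| > cutoff` or `|RIF2| > cutoff` (strict).
#' Results are ordered by `max(|RIF1|, |RIF2|)` descending, ties broken
#' lexicographically by id.
#'
#' @param t a `rif_table` from [rif_scores()].
#' @return character vector of significant TF ids.
#' @export
significant_tfs <- function(t) {
  stopifnot(inherits(t, "rif_table"))
  sig <- t[t$sig1 | t$sig2, , drop = FALSE]
  score <- pmax(abs(sig$RIF1), abs(sig$RIF2))
  sig$TF[order(-score, sig$TF)]
}
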