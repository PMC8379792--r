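#' Two-condition sample design
#'
#' Maps every sample to one of exactly two condition labels and declares which
#' label is the reference. Each condition must contain at least two samples.
#'
#' @param assignments named character vector: names are sample ids, values are
#'   condition labels.
#' @param reference the reference condition label.
#' @return an object of class `condition_design` with fields `assignments`,
#'   `reference`, `alternate`.
#' @export
condition_design <- function(assignments, reference) {
  if (is.null(names(assignments)) || any(names(assignments) == "")) {
    stop("`assignments` must be named by sample id")
  }
  if (anyDuplicated(names(assignments))) {
    stop("duplicated sample ids in design")
  }
  labels <- unique(unname(assignments))
  if (length(labels) != 2) {
    stop("exactly two condition labels required, got: ",
         paste(labels, collapse = ", "))
  }
  if (!reference %in% labels) {
    stop(sprintf("reference condition '%s' not among labels (%s)",
                 reference, paste(labels, collapse = ", ")))
  }
  counts <- table(assignments)
  if (any(counts < 2)) {
    stop("each condition needs >= 2 samples")
  }
  structure(
    list(assignments = assignments, reference = reference,
         alternate = setdiff(labels, reference)),
    class = "condition_design"
  )
}

#' Read a two-column design file
#'
#' @param path TSV with columns sample id and condition (no header, or a
#'   header line `sample<TAB>condition`).
#' @param reference the reference condition label.
#' @return a [condition_design()].
#' @export
read_design <- function(path, reference) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(as.character(df[1, ])), c("sample", "condition"))) {
    df <- df[-1, , drop = FALSE]
  }
  if (ncol(df) != 2) stop("design file must have two columns")
  condition_design(stats::setNames(as.character(df[[2]]),
                                   as.character(df[[1]])), reference)
}

# Column indices of the samples belonging to `label`, in matrix order.
design_samples <- function(m, d, label) {
  ids <- names(d$assignments)[d$assignments == label]
  missing <- setdiff(m$sample_ids, names(d$assignments))
  if (length(missing)) {
    stop("samples missing from design: ", paste(missing, collapse = ", "))
  }
  which(m$sample_ids %in% ids)
}

#' Gene-wise standardized difference of expression
#'
#' For each gene, takes the difference `s = mean(reference) - mean(alternate)`
#' of its condition means on the normalized scale, then standardizes the
#' vector `s` across genes: `diff = (s - mean(s)) / sqrt(var(s))`, with the
#' sample (n-1) variance. The result is a z-score screen: by construction
#' `diff` has mean 0 and standard deviation 1 over genes.
#'
#' @param m a normalized [expression_matrix()] with at least 2 genes.
#' @param d a [condition_design()] covering all samples of `m`.
#' @return a data frame of class `diff_table` with columns `gene`, `mean_ref`,
#'   `mean_alt`, `s`, `diff`, `avgexpr`, and attributes `reference`,
#'   `alternate`.
#' @export
reverter_diff <- function(m, d) {
  stopifnot(inherits(m, "expression_matrix"), inherits(d, "condition_design"))
  if (length(m$gene_ids) < 2) stop("need >= 2 genes to standardize")
  ref_idx <- design_samples(m, d, d$reference)
  alt_idx <- design_samples(m, d, d$alternate)
  mean_ref <- rowMeans(m$values[, ref_idx, drop = FALSE])
  mean_alt <- rowMeans(m$values[, alt_idx, drop = FALSE])
  s <- mean_ref - mean_alt
  v <- stats::var(s)
  if (v == 0) stop("degenerate contrast: zero variance of condition differences")
  out <- data.frame(
    gene = m$gene_ids,
    mean_ref = mean_ref,
    mean_alt = mean_alt,
    s = s,
    diff = (s - mean(s)) / sqrt(v),
    avgexpr = rowMeans(m$values),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "reference") <- d$reference
  attr(out, "alternate") <- d$alternate
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Classify genes as up, down, or not differentially expressed
#'
#' Three-way split of the standardized difference by a cutoff with strict
#' inequality: `up` iff `diff > cutoff`, `down` iff `diff < -cutoff`,
#' otherwise `ns` (a value exactly at the boundary is `ns`). The default
#' cutoff 1.96 mirrors the two-tailed 5% normal point used for the RIF
#' significance call; 2.57 (two-tailed 1%) is a common stricter choice.
#'
#' @param t a `diff_table` from [reverter_diff()].
#' @param cutoff positive threshold on `|diff|`; default 1.96.
#' @param tfs optional character vector of transcription-factor ids used to
#'   set the `is_tf` flag.
#' @return a data frame of class `de_classification` with columns `gene`,
#'   `diff`, `avgexpr`, `status` (up/down/ns), `is_tf`; attribute `cutoff`.
#' @export
classify_de <- function(t, cutoff = 1.96, tfs = character()) {
  stopifnot(inherits(t, "diff_table"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop("`cutoff` must be a single positive number")
  }
  status <- ifelse(t$diff > cutoff, "up",
                   ifelse(t$diff < -cutoff, "down", "ns"))
  out <- data.frame(
    gene = t$gene,
    diff = t$diff,
    avgexpr = t$avgexpr,
    status = status,
    is_tf = t$gene %in% tfs,
    stringsAsFactors = FALSE
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "reference") <- attr(t, "reference")
  attr(out, "alternate") <- attr(t, "alternate")
  class(out) <- c("de_classification", "data.frame")
  out
}

#' @export
print.de_classification <- function(x, ...) {
  tab <- table(factor(x$status, c("up", "down", "ns")))
  cat(sprintf(
    "<de_classification> %d genes at cutoff %.3g: %d up, %d down, %d ns (%d TFs)\n",
    nrow(x), attr(x, "cutoff"), tab[["up"]], tab[["down"]], tab[["ns"]],
    sum(x$is_tf)))
  invisible(x)
}
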