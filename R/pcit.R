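#' Pearson correlation matrix over a sample subset
#'
#' Correlates every pair of genes across the given samples. Genes with zero
#' variance in the subset get 0 on their off-diagonal entries (with a
#' warning); the diagonal is exactly 1.
#'
#' @param m normalized [expression_matrix()] with >= 2 genes.
#' @param samples sample ids or column indices; defaults to all samples. At
#'   least 3 samples are required.
#' @return an object of class `correlation_matrix`: list with `values`
#'   (symmetric, unit diagonal) and `node_ids`.
#' @export
correlation_matrix <- function(m, samples = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  if (is.null(samples)) samples <- m$sample_ids
  if (is.character(samples)) {
    missing <- setdiff(samples, m$sample_ids)
    if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
    idx <- match(samples, m$sample_ids)
  } else {
    idx <- samples
  }
  if (length(idx) < 3) stop("need >= 3 samples to estimate correlations")
  if (length(m$gene_ids) < 2) stop("need >= 2 genes")
  x <- t(m$values[, idx, drop = FALSE])
  flat <- apply(x, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(x))
  if (any(flat)) {
    warning("zero-variance genes (correlations set to 0): ",
            paste(m$gene_ids[flat], collapse = ", "))
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  structure(list(values = r, node_ids = m$gene_ids),
            class = "correlation_matrix")
}

# Validate or coerce a plain symmetric matrix into a correlation_matrix.
as_correlation_matrix <- function(x, node_ids = NULL) {
  if (inherits(x, "correlation_matrix")) return(x)
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  if (max(abs(x - t(x))) > 1e-12) stop("correlation matrix must be symmetric")
  if (any(abs(x) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  if (any(abs(diag(x) - 1) > 1e-12)) stop("diagonal must be 1")
  if (is.null(node_ids)) node_ids <- rownames(x)
  if (is.null(node_ids)) node_ids <- sprintf("n%d", seq_len(nrow(x)))
  structure(list(values = x, node_ids = node_ids),
            class = "correlation_matrix")
}

#' First-order partial correlation of a trio
#'
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`:
#' the correlation between x and y after conditioning on z.
#'
#' @param r_xy,r_xz,r_yz pairwise correlations in `[-1, 1]`.
#' @return the partial correlation, a single number.
#' @export
#' @examples
#' partial_correlation(0.5, 0.5, 0.5) # 1/3
partial_correlation <- function(r_xy, r_xz, r_yz) {
  stopifnot(abs(r_xy) <= 1, abs(r_xz) <= 1, abs(r_yz) <= 1)
  if (abs(r_xz) == 1 || abs(r_yz) == 1) stop("collinear trio")
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Trio tolerance: average ratio of partial to direct correlation
#'
#' `eps = (1/3) * (r_xy.z/r_xy + r_xz.y/r_xz + r_yz.x/r_yz)`. Symmetric in
#' the trio. If any direct correlation is exactly 0 the ratio is undefined
#' and the trio is non-informative: `NA` is returned with a warning (such
#' trios issue no discards inside [pcit()]).
#'
#' @inheritParams partial_correlation
#' @return the tolerance, or `NA` for a non-informative trio.
#' @export
#' @examples
#' pcit_tolerance(0.5, 0.5, 0.5) # 2/3
pcit_tolerance <- function(r_xy, r_xz, r_yz) {
  if (r_xy == 0 || r_xz == 0 || r_yz == 0) {
    warning("zero direct correlation: trio is non-informative")
    return(NA_real_)
  }
  (partial_correlation(r_xy, r_xz, r_yz) / r_xy +
   partial_correlation(r_xz, r_xy, r_yz) / r_xz +
   partial_correlation(r_yz, r_xy, r_xz) / r_yz) / 3
}

#' PCIT trio filter
#'
#' Decides which pairwise associations are significant. All off-diagonal
#' pairs start significant; for every unordered trio \{x, y, z\} the three
#' partial correlations and the trio tolerance `eps` are computed, and the
#' pair (x, y) is discarded when `|r_xy| <= |eps * r_xz|` AND
#' `|r_xy| <= |eps * r_yz|` (symmetrically for the other two pairs). A pair
#' discarded in any trio is non-significant in the result. With fewer than 3
#' nodes no trio exists and every pair stays significant. Off-diagonal
#' entries with `|r| = 1` are clamped to `+/-(1 - 1e-12)` (with a warning)
#' so partial correlations stay defined; trios containing an exactly-zero
#' direct correlation issue no discards.
#'
#' The core trio loop is compiled (O(n^3) time, O(n^2) memory) and handles a
#' few thousand nodes in minutes on one CPU.
#'
#' @param c a `correlation_matrix` (from [correlation_matrix()]) or a plain
#'   symmetric numeric matrix with unit diagonal.
#' @param eq7_variant `"corrected"` (the standard rule above, default) or
#'   `"as_printed"`, a literal variant in which the first inequality compares
#'   a leg against itself — kept only so the two can be audited side by side.
#' @return an object of class `pcit_result`: `significant` (logical symmetric
#'   matrix, FALSE diagonal), `weights` (the input correlations), `node_ids`.
#' @export
pcit <- function(c, eq7_variant = c("corrected", "as_printed")) {
  eq7_variant <- match.arg(eq7_variant)
  c <- as_correlation_matrix(c)
  r <- c$values
  off <- abs(r) >= 1 & row(r) != col(r)
  if (any(off)) {
    warning(sum(off) / 2, " collinear pair(s) clamped to +/-(1 - 1e-12)")
    r[off] <- sign(r[off]) * (1 - 1e-12)
  }
  res <- .pcit_cpp(r, eq7_variant == "corrected")
  sig <- res$significant
  dimnames(sig) <- list(c$node_ids, c$node_ids)
  structure(list(significant = sig, weights = c$values,
                 node_ids = c$node_ids,
                 skipped_trios = res$skipped_trios,
                 eq7_variant = eq7_variant),
            class = "pcit_result")
}

#' @export
print.pcit_result <- function(x, ...) {
  cat(sprintf("<pcit_result> %d nodes, %d significant associations (%s rule)\n",
              length(x$node_ids), sum(x$significant) / 2, x$eq7_variant))
  invisible(x)
}

#' Run PCIT separately on each condition's samples
#'
#' @param m normalized [expression_matrix()].
#' @param d a [condition_design()].
#' @param nodes gene/TF ids to include; default all genes in `m`.
#' @param eq7_variant passed to [pcit()].
#' @return a named list of two `pcit_result`s, one per condition (reference
#'   first).
#' @export
pcit_per_condition <- function(m, d, nodes = NULL,
                               eq7_variant = c("corrected", "as_printed")) {
  stopifnot(inherits(m, "expression_matrix"), inherits(d, "condition_design"))
  eq7_variant <- match.arg(eq7_variant)
  if (is.null(nodes)) nodes <- m$gene_ids
  missing <- setdiff(nodes, m$gene_ids)
  if (length(missing)) stop("nodes absent from matrix: ",
                            paste(missing, collapse = ", "))
  sub <- expression_matrix(m$values[nodes, , drop = FALSE], m$kind)
  out <- lapply(c(d$reference, d$alternate), function(lbl) {
    idx <- design_samples(sub, d, lbl)
    pcit(correlation_matrix(sub, idx), eq7_variant)
  })
  stats::setNames(out, c(d$reference, d$alternate))
}

#' Significant associations as an edge list
#'
#' @param p a `pcit_result`.
#' @param condition optional condition label recorded in the table.
#' @return data frame with columns `node_a`, `node_b`, `correlation` (and
#'   `condition` when given), one row per unordered significant pair,
#'   `node_a < node_b`.
#' @export
pcit_edges <- function(p, condition = NULL) {
  stopifnot(inherits(p, "pcit_result"))
  idx <- which(p$significant & upper.tri(p$significant), arr.ind = TRUE)
  out <- data.frame(
    node_a = p$node_ids[idx[, 1]],
    node_b = p$node_ids[idx[, 2]],
    correlation = p$weights[idx],
    stringsAsFactors = FALSE
  )
  swap <- out$node_a > out$node_b
  tmp <- out$node_a[swap]; out$node_a[swap] <- out$node_b[swap]
  out$node_b[swap] <- tmp
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(condition)) out$condition <- condition
  out
}

#' Read a square correlation matrix from TSV
#'
#' First column node ids, header row of the same ids.
#'
#' @param path TSV file.
#' @return a `correlation_matrix`.
#' @export
read_correlation_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[-1])
  dimnames(vals) <- list(ids, ids)
  as_correlation_matrix(vals, ids)
}
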