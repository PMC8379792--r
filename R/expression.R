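#' Construct an expression matrix
#'
#' Container for a genes x samples expression matrix. Values must be
#' nonnegative and complete; gene and sample identifiers are taken from the
#' dimnames and must be unique. The `kind` flag records whether the values are
#' raw counts or already on a normalized scale (TPM, FPKM, ...); it is never
#' guessed from the values themselves.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param kind `"counts"` or `"normalized"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids` and `kind`.
#' @export
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' expression_matrix(m, kind = "counts")
expression_matrix <- function(values, kind = c("counts", "normalized")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column %d", bad[1], bad[2]))
  }
  if (any(values < 0)) {
    stop("expression values must be nonnegative")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicated gene ids: ", paste(dups, collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    dups <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicated sample ids: ", paste(dups, collapse = ", "))
  }
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         kind = kind),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              length(x$gene_ids), length(x$sample_ids), x$kind))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Supported layouts: delimited text (genes in rows, first column the gene id,
#' header row of sample ids) and MatrixMarket coordinate format accompanied by
#' two sidecar files with one gene id / one sample id per line.
#'
#' @param path path to the matrix file.
#' @param fmt `"tsv"`, `"csv"` or `"mtx"`.
#' @param kind whether the file holds raw `"counts"` or `"normalized"` values;
#'   this is declared by the caller, never inferred.
#' @param rownames_path,colnames_path sidecar identifier files, required for
#'   `fmt = "mtx"` and ignored otherwise.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, fmt = c("tsv", "csv", "mtx"),
                            kind = c("counts", "normalized"),
                            rownames_path = NULL, colnames_path = NULL) {
  fmt <- match.arg(fmt)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  if (fmt == "mtx") {
    if (is.null(rownames_path) || is.null(colnames_path)) {
      stop("mtx input requires `rownames_path` and `colnames_path`")
    }
    vals <- as.matrix(Matrix::readMM(path))
    rn <- readLines(rownames_path)
    cn <- readLines(colnames_path)
    if (length(rn) != nrow(vals) || length(cn) != ncol(vals)) {
      stop(sprintf(
        "sidecar name files (%d rows, %d cols) do not match matrix (%d x %d)",
        length(rn), length(cn), nrow(vals), ncol(vals)))
    }
    dimnames(vals) <- list(rn, cn)
    return(expression_matrix(vals, kind))
  }
  sep <- if (fmt == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#", quote = "\"")
  if (ncol(raw) < 2) stop("expected a gene-id column plus >= 1 sample column")
  gene_ids <- as.character(raw[[1]])
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicated gene ids: ", paste(dups, collapse = ", "))
  }
  body <- raw[-1]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1]
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad], gene_ids[bad], names(body)[j]))
    }
  }
  vals <- as.matrix(body)
  rownames(vals) <- gene_ids
  expression_matrix(vals, kind)
}

#' Write an expression matrix as TSV
#'
#' Genes in rows, first column `gene`, one column per sample.
#'
#' @param m an [expression_matrix()].
#' @param path output file.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(gene = m$gene_ids, m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
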