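#' Construct an expression matrix
#'
#' Thin validated wrapper around a gene-by-sample numeric matrix. The
#' `scale` attribute records whether values are raw counts (non-negative
#' integers) or normalized log2 values, and downstream steps check it:
#' normalization requires `raw_counts`, scoring requires `normalized_log`.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids Unique identifiers; default to dimnames.
#' @param scale `"raw_counts"` or `"normalized_log"`.
#' @return A numeric matrix of class `expr_matrix` with a `scale` attribute
#'   and dimnames set to the gene/sample identifiers.
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        sample_ids = colnames(values),
                        scale = c("raw_counts", "normalized_log")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers", call. = FALSE)
  if (anyNA(values)) stop("missing values are not allowed", call. = FALSE)
  if (scale == "raw_counts" &&
      (any(values < 0) || any(values != floor(values))))
    stop("raw counts must be non-negative integers", call. = FALSE)
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

expr_scale <- function(x) attr(x, "scale", exact = TRUE)

#' @export
as.matrix.expr_matrix <- function(x, ...) {
  attr(x, "scale") <- NULL
  class(x) <- NULL
  x
}

.check_scale <- function(x, scale) {
  if (!inherits(x, "expr_matrix"))
    stop("expected an expr_matrix; see expr_matrix() or read_counts()",
         call. = FALSE)
  if (!identical(expr_scale(x), scale))
    stop("expected a matrix on the '", scale, "' scale, got '",
         expr_scale(x), "'", call. = FALSE)
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x), " genes x ", ncol(x), " samples [",
      expr_scale(x), "]\n", sep = "")
  invisible(x)
}

#' Read a gene-by-sample count matrix
#'
#' `read_counts()` reads TSV/CSV (first column gene IDs, header of sample
#' IDs; delimiter inferred from the extension or set explicitly).
#' `read_counts_mtx()` reads MatrixMarket sparse counts with separate
#' one-ID-per-line gene and sample name files.
#'
#' @param path Path to the matrix file.
#' @param sep Field delimiter; default `"\t"` unless the file ends `.csv`.
#' @param scale Scale flag to stamp on the result (counts by default).
#' @return An [expr_matrix()].
#' @export
read_counts <- function(path, sep = NULL,
                        scale = c("raw_counts", "normalized_log")) {
  scale <- match.arg(scale)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  expr_matrix(as.matrix(df), scale = scale)
}

#' @rdname read_counts
#' @param genes_path,samples_path Plain-text files with one identifier per
#'   line, in matrix row/column order.
#' @export
read_counts_mtx <- function(path, genes_path, samples_path) {
  m <- as.matrix(Matrix::readMM(path))
  gene_ids <- readLines(genes_path)
  sample_ids <- readLines(samples_path)
  expr_matrix(m, gene_ids = gene_ids, sample_ids = sample_ids,
              scale = "raw_counts")
}

#' Write an expression matrix as TSV
#'
#' Genes in rows (first column `gene_id`), samples as remaining columns.
#'
#' @param x An [expr_matrix()] (or plain matrix with dimnames).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), as.matrix(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
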