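#' Construct a cells-by-genes count matrix
#'
#' The canonical input container: a dense nonnegative integer matrix with
#' cells in rows and genes in columns, plus unique identifiers for both.
#'
#' @param counts numeric matrix (or Matrix) of nonnegative integers,
#'   cells in rows, genes in columns.
#' @param cell_ids character vector of unique cell identifiers
#'   (default: rownames or `cell_1..cell_n`).
#' @param gene_ids character vector of unique gene identifiers
#'   (default: colnames or `gene_1..gene_g`).
#' @return An object of class `scg_counts` with elements `counts`,
#'   `cell_ids`, `gene_ids`.
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("count matrix must have at least 2 cells and 2 genes")
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("count matrix contains missing or non-finite values")
  if (any(counts < 0))
    stop("count matrix contains negative values")
  if (any(counts != round(counts)))
    stop("count matrix contains non-integer values")
  if (is.null(cell_ids)) cell_ids <- rownames(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(counts)))
  if (anyDuplicated(cell_ids)) stop("cell identifiers must be unique")
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique")
  if (length(cell_ids) != nrow(counts) || length(gene_ids) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions")
  dimnames(counts) <- NULL
  structure(
    list(counts = counts,
         cell_ids = as.character(cell_ids),
         gene_ids = as.character(gene_ids)),
    class = "scg_counts")
}

#' @export
print.scg_counts <- function(x, ...) {
  cat(sprintf("<scg_counts> %d cells x %d genes, %.1f%% zeros\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(x$counts == 0)))
  invisible(x)
}

#' @export
dim.scg_counts <- function(x) dim(x$counts)

as_scg_counts <- function(X) {
  if (inherits(X, "scg_counts")) return(X)
  count_matrix(X)
}
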