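#' Weight-variance gene interpretability screen
#'
#' Traces gene importance backwards through the encoder weights. The
#' per-row standard deviation of the second-layer weights `W2`
#' (h1 x z_dim) scores each hidden unit's spread across the embedding
#' dimensions; the top `top_frac` of units are retained (`I1`). The
#' first-layer weights `W1` (d x h1) restricted to those columns are then
#' scored the same way per gene, and the top `n_top` genes are selected
#' (`I2`). Standard deviations use the population formula; ties break to
#' the lower index; "top 50%" rounds up.
#'
#' @param W1 first-layer encoder weights (d x h1) or an `scg_fit` /
#'   `scg_params` object.
#' @param W2 second-layer encoder weights (h1 x z_dim); ignored when
#'   `W1` is a fit or parameter object.
#' @param top_frac fraction of hidden units kept (default 0.5).
#' @param n_top number of genes selected (default 200).
#' @param gene_ids optional identifiers for the d genes; taken from the
#'   fit's normalized matrix when available.
#' @return `scg_genes` list: `r1`, `I1`, `r2`, `I2`,
#'   `selected_gene_ids`.
#' @export
select_genes <- function(W1, W2 = NULL, top_frac = 0.5, n_top = 200L,
                         gene_ids = NULL) {
  if (inherits(W1, "scg_fit")) {
    if (is.null(gene_ids) && !is.null(W1$norm)) gene_ids <- W1$norm$gene_ids
    W1 <- W1$params
  }
  if (inherits(W1, "scg_params")) {
    W2 <- W1$W2
    W1 <- W1$W1
  }
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  if (ncol(W1) != nrow(W2)) stop("W1 and W2 shapes are inconsistent")
  d <- nrow(W1); h1 <- nrow(W2)
  n_top <- as.integer(n_top)
  if (n_top < 1L || n_top > d)
    stop(sprintf("n_top must be in [1, %d], got %d", d, n_top))
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  pop_sd <- function(M) sqrt(rowMeans((M - rowMeans(M))^2))
  r1 <- pop_sd(W2)
  n1 <- as.integer(ceiling(h1 * top_frac))
  I1 <- order(r1, decreasing = TRUE)[seq_len(n1)]
  r2 <- pop_sd(W1[, I1, drop = FALSE])
  I2 <- order(r2, decreasing = TRUE)[seq_len(n_top)]
  structure(list(r1 = r1, I1 = I1, r2 = r2, I2 = I2,
                 selected_gene_ids = if (is.null(gene_ids)) NULL
                                     else gene_ids[I2]),
            class = "scg_genes")
}

#' @export
print.scg_genes <- function(x, ...) {
  cat(sprintf("<scg_genes> %d hidden units kept, %d genes selected\n",
              length(x$I1), length(x$I2)))
  invisible(x)
}

#' Per-cluster mean expression of selected genes
#'
#' One row per selected gene, one column per cluster; values are mean
#' normalized expression within the cluster.
#'
#' @param X an `scg_counts` object (normalized internally) or an
#'   `scg_norm` object whose columns the selection indices refer to.
#' @param labels cluster labels, length n.
#' @param genes `scg_genes` from [select_genes()], or an integer vector
#'   of column indices.
#' @return Numeric matrix (selected genes x clusters) with dimnames.
#' @export
cluster_expression_summary <- function(X, labels, genes) {
  idx <- if (inherits(genes, "scg_genes")) genes$I2 else as.integer(genes)
  if (inherits(X, "scg_norm")) {
    V <- X$values
    ids <- X$gene_ids
  } else {
    H <- normalize_counts(as_scg_counts(X))
    V <- H$values
    ids <- H$gene_ids
  }
  if (length(labels) != nrow(V)) stop("labels length differs from cell count")
  if (anyNA(labels)) stop("unknown (missing) label")
  if (max(idx) > ncol(V)) stop("gene index out of range")
  ul <- sort(unique(labels))
  out <- vapply(ul, function(u)
    colMeans(V[labels == u, idx, drop = FALSE]), numeric(length(idx)))
  out <- matrix(out, nrow = length(idx),
                dimnames = list(if (is.null(ids)) paste0("gene_", idx)
                                else ids[idx],
                                paste0("cluster_", ul)))
  out
}
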