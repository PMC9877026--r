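#' Remove genes with zero total count
#'
#' Unexpressed genes carry no information and inflate the dropout fraction;
#' they are removed before normalization. Idempotent.
#'
#' @param X an `scg_counts` object (or coercible matrix).
#' @return An `scg_counts` restricted to genes with nonzero total count,
#'   with attribute `kept_genes` giving the original column indices.
#' @export
filter_genes <- function(X) {
  X <- as_scg_counts(X)
  keep <- which(colSums(X$counts) > 0)
  if (length(keep) == 0L) stop("empty matrix after filtering")
  prev <- attr(X, "kept_genes")
  # built directly: a filtered matrix may legitimately drop to one gene
  out <- structure(
    list(counts = X$counts[, keep, drop = FALSE],
         cell_ids = X$cell_ids,
         gene_ids = X$gene_ids[keep]),
    class = "scg_counts")
  attr(out, "kept_genes") <- if (is.null(prev)) keep else prev[keep]
  out
}

#' Library-size normalize and log-transform counts
#'
#' Each cell's counts are divided by the cell total, rescaled by the median
#' total count over cells, and log-transformed:
#' `ln(1 + median_total * x_ij / rowsum_i)`. Division by the cell total
#' makes the output invariant to per-cell scaling of counts (library size);
#' the median rescale keeps values on a count-like scale; the pseudocount
#' keeps zero counts at exactly 0 (`strict = TRUE` drops the pseudocount
#' and applies the bare log to nonzero entries, mapping zeros to 0).
#'
#' @param X an `scg_counts` object (or coercible matrix).
#' @param strict logical; apply the literal log (no pseudocount) to
#'   nonzero entries. Default `FALSE`.
#' @return List with `values` (n x g numeric matrix) and `median_total`.
#' @export
normalize_counts <- function(X, strict = FALSE) {
  X <- as_scg_counts(X)
  totals <- rowSums(X$counts)
  if (any(totals == 0)) {
    bad <- which(totals == 0)
    stop(sprintf("cell(s) with zero total count: %s",
                 paste(X$cell_ids[bad], collapse = ", ")))
  }
  med <- stats::median(totals)
  scaled <- med * X$counts / totals
  if (strict) {
    H <- matrix(0, nrow(scaled), ncol(scaled))
    nz <- scaled > 0
    H[nz] <- log(scaled[nz])
  } else {
    H <- log1p(scaled)
  }
  list(values = H, median_total = med,
       cell_ids = X$cell_ids, gene_ids = X$gene_ids)
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Per-gene dispersion (variance / mean) is z-scored within 20
#' equal-frequency bins of the gene mean, so that variability is judged
#' relative to genes of comparable abundance. The top `d` genes by this
#' normalized dispersion are retained, in descending rank order.
#'
#' @param H list from [normalize_counts()] (or a bare numeric matrix).
#' @param d number of genes to retain.
#' @param n_bins number of equal-frequency mean bins (default 20).
#' @return An object of class `scg_norm`: `values` (n x d), `gene_index`
#'   (retained column -> input column), `gene_ids`, `d`, `median_total`,
#'   `dispersion` (normalized dispersion of retained genes).
#' @export
select_hvg <- function(H, d = 500L, n_bins = 20L) {
  if (is.matrix(H)) H <- list(values = H, median_total = NA_real_,
                              cell_ids = NULL, gene_ids = NULL)
  V <- H$values
  g <- ncol(V)
  if (d <= 0 || d > g) stop(sprintf("d must be in [1, %d], got %d", g, d))
  mu <- colMeans(V)
  vr <- apply(V, 2L, stats::var)
  disp <- ifelse(mu > 0, vr / mu, 0)
  norm_disp <- normalized_dispersion(mu, disp, n_bins)
  ord <- order(norm_disp, decreasing = TRUE)[seq_len(d)]
  gene_ids <- H$gene_ids
  structure(
    list(values = V[, ord, drop = FALSE],
         gene_index = ord,
         gene_ids = if (is.null(gene_ids)) NULL else gene_ids[ord],
         cell_ids = H$cell_ids,
         d = as.integer(d),
         median_total = H$median_total,
         dispersion = norm_disp[ord]),
    class = "scg_norm")
}

# z-score dispersion within equal-frequency bins of the mean; degenerate
# bins (sd 0 or singleton) get z = 0 so constant genes never rank high
normalized_dispersion <- function(mu, disp, n_bins) {
  g <- length(mu)
  n_bins <- max(1L, min(n_bins, g))
  qs <- stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L))
  bins <- cut(mu, breaks = unique(qs), include.lowest = TRUE)
  z <- numeric(g)
  for (b in levels(bins)) {
    idx <- which(bins == b)
    m <- mean(disp[idx])
    s <- stats::sd(disp[idx])
    z[idx] <- if (length(idx) < 2L || !is.finite(s) || s == 0) 0
              else (disp[idx] - m) / s
  }
  z
}

#' Full preprocessing: filter, normalize, select HVGs
#'
#' @inheritParams filter_genes
#' @inheritParams normalize_counts
#' @param d number of highly variable genes to retain (capped at the
#'   number of expressed genes).
#' @param n_bins mean bins for dispersion normalization.
#' @return An `scg_norm` object (see [select_hvg()]); `gene_index` maps
#'   back to columns of the *filtered* matrix and `gene_ids` to the
#'   original identifiers.
#' @export
preprocess_counts <- function(X, d = 500L, strict = FALSE, n_bins = 20L) {
  Xf <- filter_genes(X)
  H <- normalize_counts(Xf, strict = strict)
  select_hvg(H, d = min(as.integer(d), ncol(H$values)), n_bins = n_bins)
}

#' @export
print.scg_norm <- function(x, ...) {
  cat(sprintf("<scg_norm> %d cells x %d HVGs (median total %.0f)\n",
              nrow(x$values), x$d, x$median_total))
  invisible(x)
}
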