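#' Read a count matrix from disk
#'
#' Supports dense CSV/TSV (orientation set by `cells_in_rows`),
#' MatrixMarket MTX with companion gene/barcode text files, and a
#' 10x-style triplet directory (`matrix.mtx`, `features.tsv` or
#' `genes.tsv`, `barcodes.tsv`; genes in rows, transposed on read).
#'
#' @param path file (csv/mtx) or directory (tenx_dir).
#' @param format one of `"csv"`, `"mtx"`, `"tenx_dir"`.
#' @param cells_in_rows for CSV: `TRUE` (default) if rows are cells.
#' @param genes_file,barcodes_file companion files for `format = "mtx"`
#'   (defaults: same stem with `.genes.txt` / `.barcodes.txt`, optional).
#' @param sep CSV field separator (default `","`; use `"\t"` for TSV).
#' @return An `scg_counts` object.
#' @export
read_counts <- function(path, format = c("csv", "mtx", "tenx_dir"),
                        cells_in_rows = TRUE, genes_file = NULL,
                        barcodes_file = NULL, sep = ",") {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            row.names = 1L, check.names = FALSE)
    M <- as.matrix(df)
    if (!is.numeric(M)) stop(sprintf("non-numeric entries in %s", path))
    if (!cells_in_rows) M <- t(M)
    return(count_matrix(M))
  }
  if (format == "mtx") {
    M <- as.matrix(read_mtx_checked(path))
    gene_ids <- if (!is.null(genes_file)) readLines(genes_file) else NULL
    cell_ids <- if (!is.null(barcodes_file)) readLines(barcodes_file) else NULL
    return(count_matrix(t(M), cell_ids = cell_ids, gene_ids = gene_ids))
  }
  mtx <- file.path(path, "matrix.mtx")
  feat <- file.path(path, "features.tsv")
  if (!file.exists(feat)) feat <- file.path(path, "genes.tsv")
  bc <- file.path(path, "barcodes.tsv")
  if (!file.exists(mtx)) stop(sprintf("no matrix.mtx in %s", path))
  M <- as.matrix(read_mtx_checked(mtx))
  gene_ids <- if (file.exists(feat))
    utils::read.table(feat, sep = "\t", stringsAsFactors = FALSE)[[1L]]
  else NULL
  cell_ids <- if (file.exists(bc)) readLines(bc) else NULL
  count_matrix(t(M), cell_ids = cell_ids, gene_ids = gene_ids)
}

# readMM tolerates a wrong nnz in the size line; validate it explicitly
read_mtx_checked <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
  hdr <- scan(text = body[1L], quiet = TRUE)
  if (length(hdr) == 3L && hdr[3L] != length(body) - 1L)
    stop(sprintf("%s: header declares %d entries but file has %d (line 1)",
                 path, hdr[3L], length(body) - 1L))
  Matrix::readMM(path)
}

#' Write a count matrix as MatrixMarket MTX plus id files
#'
#' Written in the 10x convention (genes in rows); companions
#' `<stem>.genes.txt` and `<stem>.barcodes.txt` hold the identifiers.
#'
#' @param X `scg_counts` object.
#' @param path output `.mtx` path.
#' @return Invisibly, the paths written.
#' @export
write_counts_mtx <- function(X, path) {
  X <- as_scg_counts(X)
  M <- Matrix::Matrix(t(X$counts), sparse = TRUE)
  Matrix::writeMM(M, path)
  stem <- sub("\\.mtx$", "", path)
  gf <- paste0(stem, ".genes.txt")
  bf <- paste0(stem, ".barcodes.txt")
  writeLines(X$gene_ids, gf)
  writeLines(X$cell_ids, bf)
  invisible(c(path, gf, bf))
}

#' Write fit results to a directory
#'
#' Writes `labels.csv` (cell_id, cluster), `embedding.csv` (n x z_dim),
#' `losses.tsv` (per-iteration component losses), `config.json`
#' (resolved configuration + seed) and `checkpoint.rds` (model
#' parameters) with `checkpoint.json` manifest. Overwrites existing
#' files.
#'
#' @param result `scg_fit` object.
#' @param dir output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_results <- function(result, dir) {
  if (!inherits(result, "scg_fit")) stop("result must be an scg_fit")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- result$cell_ids
  if (is.null(ids)) ids <- paste0("cell_", seq_along(result$labels))
  utils::write.csv(data.frame(cell_id = ids, cluster = result$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  emb <- as.data.frame(result$Z)
  names(emb) <- paste0("z", seq_len(ncol(emb)))
  utils::write.csv(cbind(cell_id = ids, emb),
                   file.path(dir, "embedding.csv"), row.names = FALSE)
  if (!is.null(result$history))
    utils::write.table(result$history, file.path(dir, "losses.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- result$config
  jsonlite::write_json(
    list(config = unclass(cfg), weights = unclass(result$weights),
         K = nrow(result$centers), init_strategy = result$init$strategy),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(result$params, file.path(dir, "checkpoint.rds"))
  p <- result$params
  jsonlite::write_json(
    list(shapes = lapply(p, dim), decoder = attr(p, "decoder"),
         z_dim = attr(p, "z_dim"), h1 = attr(p, "h1"),
         seed = cfg$seed),
    file.path(dir, "checkpoint.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write the retained gene list
#'
#' One gene identifier per line, in descending HVG rank order.
#'
#' @param Xn `scg_norm` object.
#' @param path output text file.
#' @export
write_gene_list <- function(Xn, path) {
  ids <- Xn$gene_ids
  if (is.null(ids)) ids <- paste0("gene_", Xn$gene_index)
  writeLines(ids, path)
  invisible(path)
}

#' Read / write a run configuration file
#'
#' YAML or JSON (by extension). Unknown keys are rejected; known keys
#' override the defaults of [train_config()], [loss_weights()] and the
#' pipeline arguments of [scgcae()].
#'
#' @param path config file path.
#' @return A named list with elements `cfg` (`scg_config`),
#'   `w` (`scg_weights`) and `pipeline` (d, k, steps, alpha, K,
#'   graph_type, decoder).
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_keys <- names(formals(train_config))
  w_keys <- c("gamma1", "gamma2", "gamma3")
  pipe_keys <- c("K", "d", "k", "steps", "alpha", "graph_type", "decoder")
  unknown <- setdiff(names(raw), c(cfg_keys, w_keys, pipe_keys))
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- do.call(train_config, raw[intersect(names(raw), cfg_keys)])
  w <- do.call(loss_weights, raw[intersect(names(raw), w_keys)])
  list(cfg = cfg, w = w, pipeline = raw[intersect(names(raw), pipe_keys)])
}
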