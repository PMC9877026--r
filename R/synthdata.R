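#' Simulate a clustered scRNA-seq count matrix
#'
#' Generates K cell populations with distinct multinomial
#' gene-expression programs. Each program is a shared baseline with
#' `separation`-fold enrichment on a disjoint marker block; cell i in
#' population u draws an integer library size from `lib_size_range` and
#' counts from `Multinomial(n_i, m_i)` with
#' `m_i` proportional to `pi_i * V_u`, where the retention probability
#' `pi_ij = 1 - exp(-lambda * V_uj)` decreases dropout for highly
#' expressed genes and `dropout_strength` blends it with no-dropout
#' (`strength 0` means every gene retained in expectation). Optional
#' batches apply per-batch log-normal multiplicative gene effects before
#' renormalization. Bit-reproducible under a fixed seed.
#'
#' @param n number of cells.
#' @param g number of genes (>= 10).
#' @param K number of populations (`n >= K >= 1`).
#' @param separation fold-change of marker genes over baseline
#'   (effect size; default 8).
#' @param lib_size_range integer range of per-cell totals
#'   (default `c(1000, 2500)`).
#' @param dropout_strength in `[0, 1]`; 0 disables dropout (default 0.3).
#' @param markers_per_cluster marker-block size per population
#'   (default 10).
#' @param n_batches number of batches (default 1).
#' @param batch_effect log-normal sd of per-batch gene scalings
#'   (default 0).
#' @param lambda dropout saturation rate; default `g`, so
#'   `lambda * V` is O(1) for a typical gene.
#' @param seed integer seed.
#' @return `scg_sim` list: `counts` (`scg_counts`), `labels` (1..K),
#'   `batch` (1..n_batches), `programs` (K x g, rows sum to 1),
#'   `retention` (K x g applied retention probabilities; per-cell rates
#'   follow via `labels`), `marker_genes` (list of marker index blocks),
#'   `seed`, `params`.
#' @export
simulate_counts <- function(n, g, K, separation = 8,
                            lib_size_range = c(1000L, 2500L),
                            dropout_strength = 0.3,
                            markers_per_cluster = 10L,
                            n_batches = 1L, batch_effect = 0,
                            lambda = g, seed = 1L) {
  n <- as.integer(n); g <- as.integer(g); K <- as.integer(K)
  if (K < 1L || n < K) stop("need n >= K >= 1")
  if (g < 10L) stop("need g >= 10")
  if (dropout_strength < 0 || dropout_strength > 1)
    stop("dropout_strength must be in [0, 1]")
  if (K * markers_per_cluster > g)
    stop("marker blocks exceed gene count")
  if (separation <= 0) stop("separation must be positive")
  set.seed(seed)

  baseline <- stats::rgamma(g, shape = 2, rate = 2) + 0.05
  marker_genes <- split(seq_len(K * markers_per_cluster),
                        rep(seq_len(K), each = markers_per_cluster))
  programs <- matrix(baseline, K, g, byrow = TRUE)
  for (u in seq_len(K)) programs[u, marker_genes[[u]]] <-
      programs[u, marker_genes[[u]]] * separation
  programs <- programs / rowSums(programs)

  retention <- 1 - exp(-lambda * programs)
  retention <- (1 - dropout_strength) + dropout_strength * retention

  labels <- sample(rep(seq_len(K), length.out = n))
  batch <- rep(seq_len(n_batches), length.out = n)
  batch_scale <- matrix(1, n_batches, g)
  if (n_batches > 1L && batch_effect > 0)
    batch_scale <- matrix(stats::rlnorm(n_batches * g, 0, batch_effect),
                          n_batches, g)

  lib <- sample(seq(lib_size_range[1L], lib_size_range[2L]), n,
                replace = TRUE)
  counts <- matrix(0, n, g)
  for (i in seq_len(n)) {
    m <- programs[labels[i], ] * retention[labels[i], ] *
      batch_scale[batch[i], ]
    counts[i, ] <- stats::rmultinom(1L, lib[i], m / sum(m))
  }
  expressed <- colSums(counts) > 0
  if (!all(expressed)) {
    # guarantee a valid CountMatrix: deterministically add one count of
    # any silent gene to the first cell of population 1
    for (j in which(!expressed)) counts[1L, j] <- counts[1L, j] + 1L
  }
  cm <- count_matrix(counts,
                     cell_ids = sprintf("cell_%04d", seq_len(n)),
                     gene_ids = sprintf("gene_%04d", seq_len(g)))
  structure(list(counts = cm, labels = labels, batch = batch,
                 programs = programs, retention = retention,
                 marker_genes = marker_genes, lib_sizes = lib,
                 seed = as.integer(seed),
                 params = list(n = n, g = g, K = K,
                               separation = separation,
                               lib_size_range = lib_size_range,
                               dropout_strength = dropout_strength,
                               markers_per_cluster = markers_per_cluster,
                               n_batches = n_batches,
                               batch_effect = batch_effect,
                               lambda = lambda)),
            class = "scg_sim")
}

#' @export
print.scg_sim <- function(x, ...) {
  cat(sprintf("<scg_sim> %d cells x %d genes, K = %d (seed %d)\n",
              x$params$n, x$params$g, x$params$K, x$seed))
  invisible(x)
}

#' Small frozen reference dataset
#'
#' 60 cells, 100 genes, 3 well-separated populations at a fixed seed;
#' the regression anchor for the golden-file tests and the worked
#' example.
#'
#' @return `scg_sim` object (see [simulate_counts()]).
#' @export
worked_fixture <- function() {
  simulate_counts(n = 60L, g = 100L, K = 3L, separation = 8,
                  lib_size_range = c(1000L, 2000L),
                  dropout_strength = 0.3, markers_per_cluster = 8L,
                  seed = 101L)
}
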