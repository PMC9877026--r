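#' Initialize cluster centers on the embedding
#'
#' Runs k-means on the embedding (data-distribution view) and/or spectral
#' clustering on the PPMI affinity (graph-structure view). With
#' `strategy = "auto"` both partitions are computed and the one with the
#' higher mean silhouette width on Z wins; silhouette is label-free, so
#' the selection needs no ground truth. Spectral centers are the
#' per-cluster means of Z. Any empty cluster is re-seeded at the point
#' farthest from its nearest center.
#'
#' @param Z embedding matrix (n x z_dim).
#' @param K number of clusters, `K <= n`.
#' @param strategy `"auto"` (default), `"kmeans"` or `"spectral"`.
#' @param graph `scg_graph`/`scg_ppmi` object or affinity matrix;
#'   required for the spectral strategies.
#' @param seed integer seed (k-means restarts are stochastic).
#' @return `scg_clust` list: `centers` (K x z_dim), `labels`
#'   (initial hard labels), `strategy` (the one actually used),
#'   `silhouette` (named vector when `strategy = "auto"`).
#' @export
init_centers <- function(Z, K, strategy = c("auto", "kmeans", "spectral"),
                         graph = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  K <- as.integer(K)
  if (K > n) stop(sprintf("K = %d exceeds number of cells (%d)", K, n))
  if (K < 1L) stop("K must be >= 1")
  need_graph <- strategy %in% c("auto", "spectral")
  A <- NULL
  if (need_graph) {
    if (is.null(graph)) {
      if (strategy == "spectral") stop("spectral strategy requires `graph`")
      strategy <- "kmeans"   # auto without a graph degrades to kmeans
    } else {
      A <- if (inherits(graph, "scg_graph") || inherits(graph, "scg_ppmi"))
        graph$A else as.matrix(graph)
    }
  }
  km_lab <- sp_lab <- NULL
  if (strategy %in% c("auto", "kmeans")) {
    set.seed(seed)
    km_lab <- stats::kmeans(Z, centers = K, nstart = 10L,
                            iter.max = 100L)$cluster
  }
  if (strategy %in% c("auto", "spectral") && !is.null(A))
    sp_lab <- spectral_labels(A, K, seed = seed)
  sil <- NULL
  if (strategy == "auto" && !is.null(sp_lab)) {
    sil <- c(kmeans = safe_asw(Z, km_lab), spectral = safe_asw(Z, sp_lab))
    if (sil["spectral"] > sil["kmeans"]) {
      labels <- sp_lab; strategy <- "spectral"
    } else {
      labels <- km_lab; strategy <- "kmeans"
    }
  } else {
    labels <- if (is.null(sp_lab)) km_lab else sp_lab
  }
  centers <- centers_from_labels(Z, labels, K)
  structure(list(centers = centers, labels = labels,
                 strategy = strategy, silhouette = sil),
            class = "scg_clust")
}

safe_asw <- function(Z, labels) {
  if (length(unique(labels)) < 2L) return(-1)
  asw(Z, labels)
}

# spectral clustering on an affinity matrix: leading K eigenvectors of
# D^{-1/2} A D^{-1/2}, rows normalized to unit length, then k-means
spectral_labels <- function(A, K, seed = 1L) {
  deg <- rowSums(A)
  deg[deg <= 0] <- 1e-12
  s <- 1 / sqrt(deg)
  L <- A * outer(s, s)
  ev <- eigen(L, symmetric = TRUE)
  V <- ev$vectors[, seq_len(K), drop = FALSE]
  nrm <- sqrt(rowSums(V^2))
  nrm[nrm == 0] <- 1
  V <- V / nrm
  set.seed(seed + 1L)
  stats::kmeans(V, centers = K, nstart = 10L, iter.max = 100L)$cluster
}

# per-cluster means; empty clusters re-seeded at the point farthest from
# its nearest center
centers_from_labels <- function(Z, labels, K) {
  centers <- matrix(0, K, ncol(Z))
  for (u in seq_len(K)) {
    idx <- which(labels == u)
    if (length(idx) > 0L)
      centers[u, ] <- colMeans(Z[idx, , drop = FALSE])
  }
  empty <- setdiff(seq_len(K), unique(labels))
  for (u in empty) {
    filled <- setdiff(seq_len(K), empty)
    d2 <- squared_distances(Z, centers[filled, , drop = FALSE])
    far <- which.max(apply(d2, 1L, min))
    centers[u, ] <- Z[far, ]
    empty <- setdiff(empty, u)
  }
  centers
}

#' Student-t soft cluster assignment
#'
#' `q_iu = (1 + ||z_i - mu_u||^2)^{-1} / sum_k (1 + ||z_i - mu_k||^2)^{-1}`:
#' the similarity of every cell to every center under a t-kernel with one
#' degree of freedom. Rows sum to 1.
#'
#' @param Z embedding matrix (n x z_dim).
#' @param mu center matrix (K x z_dim) or `scg_clust` object.
#' @return Soft assignment matrix Q (n x K).
#' @export
soft_assign <- function(Z, mu) {
  Z <- as.matrix(Z)
  M <- if (inherits(mu, "scg_clust")) mu$centers else as.matrix(mu)
  if (ncol(Z) != ncol(M)) stop("Z and centers disagree on dimension")
  W <- 1 / (1 + squared_distances(Z, M))
  W / rowSums(W)
}

#' Auxiliary target distribution
#'
#' Sharpens the soft assignment: `p_iu` is proportional to
#' `q_iu^2 / f_u` with `f_u = sum_i q_iu`, renormalized per cell.
#' Squaring pushes each cell toward its dominant cluster while the
#' `1/f_u` factor counteracts large clusters absorbing everything.
#'
#' @param Q soft assignment matrix (n x K).
#' @return Target matrix P (n x K), rows summing to 1.
#' @export
target_distribution <- function(Q) {
  Q <- as.matrix(Q)
  f <- colSums(Q)
  P <- sweep(Q^2, 2L, f, "/")
  P / rowSums(P)
}

#' KL clustering loss
#'
#' `L_c = sum_i sum_u p_iu ln(p_iu / q_iu)`, the Kullback-Leibler
#' divergence of Q from the target P (summed over cells; `0 ln 0 = 0`).
#'
#' @param P target distribution (n x K).
#' @param Q soft assignment (n x K).
#' @return Scalar loss, nonnegative.
#' @export
clustering_loss <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("P and Q shapes differ")
  if (any(Q <= 0 & P > 0)) stop("q_iu = 0 where p_iu > 0")
  idx <- P > 0
  sum(P[idx] * log(P[idx] / Q[idx]))
}

#' Hard labels from soft assignments
#'
#' `label_i = argmax_u q_iu`; ties go to the smaller cluster index.
#'
#' @param Q soft assignment matrix (n x K).
#' @return Integer label vector (1-based cluster indices).
#' @export
hard_labels <- function(Q) {
  max.col(as.matrix(Q), ties.method = "first")
}
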