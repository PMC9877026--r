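#' Binary k-nearest-neighbour cell graph
#'
#' Each cell is linked to its `k` nearest cells (self included) by
#' Euclidean distance in the normalized expression space. Every row has
#' exactly `k` ones and the diagonal is always 1; ties are broken by the
#' smaller cell index (with self always first), so the graph is
#' deterministic even with duplicated cells.
#'
#' @param Xhat an `scg_norm` object or numeric matrix (cells in rows).
#' @param k neighbourhood size, `1 <= k <= n`.
#' @return `scg_knn` object: binary `adjacency` (n x n), `k`.
#' @export
build_knn <- function(Xhat, k = 15L) {
  V <- if (inherits(Xhat, "scg_norm")) Xhat$values else as.matrix(Xhat)
  n <- nrow(V)
  k <- as.integer(k)
  if (k < 1L || k > n) stop(sprintf("k must be in [1, %d], got %d", n, k))
  D2 <- squared_distances(V, V)
  diag(D2) <- -Inf            # self always the first neighbour
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D2[i, ], seq_len(n))[seq_len(k)]
    K[i, nb] <- 1
  }
  structure(list(adjacency = K, k = k), class = "scg_knn")
}

# pairwise squared Euclidean distances between rows of A and rows of B
squared_distances <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Random surfing over the KNN graph
#'
#' Iterates the restart random walk `P_s = alpha * P_{s-1} K + (1 - alpha) I`
#' from `P_0 = I` and accumulates `U = sum_{s=1..S} P_s`, the multi-step
#' reachability of every cell from every other. `1 - alpha` is the restart
#' probability. By default `K` is row-normalized to a genuine transition
#' matrix (each row of every `P_s` then sums to 1); `stochastic = FALSE`
#' keeps the binary adjacency in the recursion.
#'
#' @param K an `scg_knn` object (or square nonnegative matrix).
#' @param steps number of surfing steps `S >= 1` (default 2).
#' @param alpha walk-continuation probability in (0, 1], default 0.98.
#' @param stochastic row-normalize `K` first (default `TRUE`).
#' @param method `"recursion"` iterates the update; `"closed_form"`
#'   evaluates the unrolled power form. The two agree to machine
#'   precision.
#' @return `scg_surf` object: `U` (n x n), `alpha`, `steps`.
#' @export
random_surf <- function(K, steps = 2L, alpha = 0.98, stochastic = TRUE,
                        method = c("recursion", "closed_form")) {
  method <- match.arg(method)
  A <- if (inherits(K, "scg_knn")) K$adjacency else as.matrix(K)
  n <- nrow(A)
  if (ncol(A) != n) stop("K must be square")
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (stochastic) {
    rs <- rowSums(A)
    if (any(rs == 0)) stop("K has a row with no neighbours")
    A <- A / rs
  }
  I <- diag(n)
  if (method == "recursion") {
    P <- I
    U <- matrix(0, n, n)
    for (s in seq_len(steps)) {
      P <- alpha * (P %*% A) + (1 - alpha) * I
      U <- U + P
    }
  } else {
    # P_s = alpha^s K^s + (1-alpha) sum_{t=1..s} alpha^{s-t} K^{s-t}
    pw <- vector("list", steps + 1L)
    pw[[1L]] <- I
    for (s in seq_len(steps)) pw[[s + 1L]] <- pw[[s]] %*% A
    U <- matrix(0, n, n)
    for (s in seq_len(steps)) {
      P <- alpha^s * pw[[s + 1L]]
      for (t in seq_len(s))
        P <- P + (1 - alpha) * alpha^(s - t) * pw[[s - t + 1L]]
      U <- U + P
    }
  }
  structure(list(U = U, alpha = alpha, steps = steps), class = "scg_surf")
}

#' PPMI affinity from accumulated transition probabilities
#'
#' Positive pointwise mutual information of the co-occurrence matrix `U`:
#' `A_ij = max(ln(U_ij * theta / (row_i * col_j)), 0)` with
#' `theta = sum(U)`; zero co-occurrence maps to affinity 0. PPMI upweights
#' cell pairs reached more often than expected under independence, i.e.
#' cells of the same population. Invariant to positive scaling of `U`.
#' The raw PPMI of an asymmetric `U` is asymmetric; by default the result
#' is symmetrized as `(A + t(A)) / 2` to form an undirected weighted
#' graph.
#'
#' @param U an `scg_surf` object (or nonnegative square matrix).
#' @param symmetrize average with the transpose (default `TRUE`).
#' @return `scg_ppmi` object: `A` (n x n, nonnegative), `theta`,
#'   `row_sums`, `col_sums`, `symmetrized`.
#' @export
ppmi <- function(U, symmetrize = TRUE) {
  M <- if (inherits(U, "scg_surf")) U$U else as.matrix(U)
  if (any(M < 0)) stop("U must be nonnegative")
  theta <- sum(M)
  if (theta <= 0) stop("U has zero total sum")
  r <- rowSums(M)
  cs <- colSums(M)
  A <- matrix(0, nrow(M), ncol(M))
  nz <- M > 0
  A[nz] <- log(M[nz] * theta / (outer(r, cs)[nz]))
  A[A < 0] <- 0
  if (symmetrize) A <- (A + t(A)) / 2
  structure(list(A = A, theta = theta, row_sums = r, col_sums = cs,
                 symmetrized = symmetrize),
            class = "scg_ppmi")
}

#' Degree-normalize the cell graph for graph convolution
#'
#' Computes `D = diag((I + A) 1)` and the symmetrically normalized graph
#' `Abar = D^{-1/2} A D^{-1/2}` (literal mode, default). With
#' `renormalize = TRUE` the self-loop enters the numerator too:
#' `Abar = D^{-1/2} (A + I) D^{-1/2}` (standard GCN renormalization).
#'
#' @param A an `scg_ppmi` object (or nonnegative square matrix).
#' @param renormalize include the self-loop in the numerator.
#' @return `scg_graph` object: `Abar`, `degrees`, `A` (the unnormalized
#'   affinity, kept for spectral initialization and the reconstruction
#'   target), `renormalized`.
#' @export
normalize_graph <- function(A, renormalize = FALSE) {
  M <- if (inherits(A, "scg_ppmi")) A$A else as.matrix(A)
  n <- nrow(M)
  deg <- 1 + rowSums(M)          # (I + A) row sums
  if (any(deg <= 0)) stop("zero degree in (I + A)")
  s <- 1 / sqrt(deg)
  num <- if (renormalize) M + diag(n) else M
  Abar <- num * outer(s, s)      # D^{-1/2} num D^{-1/2}
  structure(list(Abar = Abar, degrees = deg, A = M,
                 renormalized = renormalize),
            class = "scg_graph")
}

#' Build the full cell-PPMI graph from normalized expression
#'
#' Convenience composition: KNN graph, random surfing, PPMI, degree
#' normalization.
#'
#' @inheritParams build_knn
#' @inheritParams random_surf
#' @inheritParams ppmi
#' @inheritParams normalize_graph
#' @param graph_type `"ppmi"` (default) or `"knn"`, which skips surfing
#'   and PPMI and uses the symmetrized binary KNN adjacency as the
#'   affinity (ablation mode).
#' @return `scg_graph` object (see [normalize_graph()]).
#' @export
build_cell_graph <- function(Xhat, k = 15L, steps = 2L, alpha = 0.98,
                             stochastic = TRUE, symmetrize = TRUE,
                             renormalize = FALSE,
                             graph_type = c("ppmi", "knn")) {
  graph_type <- match.arg(graph_type)
  K <- build_knn(Xhat, k = k)
  if (graph_type == "knn") {
    A <- K$adjacency
    diag(A) <- 0
    if (symmetrize) A <- pmax(A, t(A))
    return(normalize_graph(A, renormalize = renormalize))
  }
  U <- random_surf(K, steps = steps, alpha = alpha, stochastic = stochastic)
  normalize_graph(ppmi(U, symmetrize = symmetrize),
                  renormalize = renormalize)
}
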