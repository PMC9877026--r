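#' Clustering agreement and geometry metrics
#'
#' Normalized mutual information, adjusted Rand index, average silhouette
#' width, Davies-Bouldin index and V-measure, computed from first
#' principles (natural logarithms throughout; NMI normalizes by the
#' geometric mean of the two entropies).
#'
#' @param l integer/character predicted label vector.
#' @param lG ground-truth label vector of the same length.
#' @return Scalar metric value.
#' @name clustering-metrics
NULL

contingency <- function(l, lG) {
  if (length(l) != length(lG)) stop("label vectors differ in length")
  table(factor(l), factor(lG))
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' @rdname clustering-metrics
#' @export
nmi <- function(l, lG) {
  N <- contingency(l, lG)
  n <- sum(N)
  a <- rowSums(N); b <- colSums(N)
  nz <- N > 0
  mi <- sum(N[nz] * log(N[nz] * n / outer(a, b)[nz]))
  ha <- -sum(xlogx(a / n)) * n   # sum a log(a/n) form, sign folded below
  hb <- -sum(xlogx(b / n)) * n
  if (ha == 0 || hb == 0) return(as.numeric(mi == 0 && ha == hb))
  mi / sqrt(ha * hb)
}

#' @rdname clustering-metrics
#' @export
ari <- function(l, lG) {
  N <- contingency(l, lG)
  n <- sum(N)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(N))
  sum_a <- sum(comb2(rowSums(N)))
  sum_b <- sum(comb2(colSums(N)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' @rdname clustering-metrics
#' @param X numeric matrix of points (rows) for the geometric metrics.
#' @param labels cluster labels for the rows of `X`.
#' @export
asw <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.vector(labels)
  ul <- unique(labels)
  if (length(ul) < 2L) stop("silhouette needs at least 2 clusters")
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  idx_by <- split(seq_len(n), labels)
  for (i in seq_len(n)) {
    own <- idx_by[[as.character(labels[i])]]
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (length(own) - 1L)
    b <- min(vapply(idx_by[setdiff(names(idx_by),
                                   as.character(labels[i]))],
                    function(j) mean(D[i, j]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' @rdname clustering-metrics
#' @export
dbi <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.vector(labels)
  ul <- sort(unique(labels))
  if (length(ul) < 2L) stop("DBI needs at least 2 clusters")
  Kn <- length(ul)
  centroids <- matrix(0, Kn, ncol(X))
  for (i in seq_len(Kn))
    centroids[i, ] <- colMeans(X[labels == ul[i], , drop = FALSE])
  S <- vapply(seq_len(Kn), function(i) {
    pts <- X[labels == ul[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2L, centroids[i, ])^2)))
  }, numeric(1))
  E <- as.matrix(stats::dist(centroids))
  off <- E[upper.tri(E)]
  if (any(off == 0)) stop("coincident cluster centroids: DBI undefined")
  mean(vapply(seq_len(Kn), function(i)
    max(((S[i] + S[-i]) / E[i, -i])), numeric(1)))
}

#' @rdname clustering-metrics
#' @export
v_measure <- function(l, lG) {
  N <- contingency(l, lG)
  n <- sum(N)
  # H(truth | predicted) and marginal entropies, natural log
  hc_given_k <- -sum(xlogx(N / n)) + sum(xlogx(rowSums(N) / n))
  hk_given_c <- -sum(xlogx(N / n)) + sum(xlogx(colSums(N) / n))
  h_c <- -sum(xlogx(colSums(N) / n))
  h_k <- -sum(xlogx(rowSums(N) / n))
  h <- if (h_c == 0) 1 else 1 - hc_given_k / h_c
  cpl <- if (h_k == 0) 1 else 1 - hk_given_c / h_k
  if (h + cpl == 0) return(0)
  2 * h * cpl / (h + cpl)
}

#' All clustering metrics at once
#'
#' @param l predicted labels.
#' @param lG ground-truth labels (optional; agreement metrics skipped if
#'   absent).
#' @param X optional point matrix (e.g. the embedding) for ASW/DBI.
#' @return Named list of metric values.
#' @export
cluster_metrics <- function(l, lG = NULL, X = NULL) {
  out <- list()
  if (!is.null(lG)) {
    out$nmi <- nmi(l, lG)
    out$ari <- ari(l, lG)
    out$v_measure <- v_measure(l, lG)
  }
  if (!is.null(X) && length(unique(l)) > 1L) {
    out$asw <- asw(X, l)
    out$dbi <- tryCatch(dbi(X, l), error = function(e) NA_real_)
  }
  out
}
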