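# Independent scalar-loop oracles used across tests. These deliberately
# avoid matrix algebra so they cannot share a bug with the implementation.

oracle_ppmi <- function(U) {
  n <- nrow(U); m <- ncol(U)
  theta <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) theta <- theta + U[i, j]
  r <- numeric(n); cs <- numeric(m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    r[i] <- r[i] + U[i, j]
    cs[j] <- cs[j] + U[i, j]
  }
  A <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (U[i, j] > 0) {
      v <- log(U[i, j] * theta / (r[i] * cs[j]))
      A[i, j] <- max(v, 0)
    }
  }
  A
}

oracle_encode <- function(X, Abar, W1, W2) {
  mm <- function(A, B) {
    C <- matrix(0, nrow(A), ncol(B))
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(B)))
      for (k in seq_len(ncol(A))) C[i, j] <- C[i, j] + A[i, k] * B[k, j]
    C
  }
  rl <- function(M) { M[M < 0] <- 0; M }
  rl(mm(Abar, mm(rl(mm(Abar, mm(X, W1))), W2)))
}

oracle_soft_assign <- function(Z, mu) {
  n <- nrow(Z); K <- nrow(mu)
  Q <- matrix(0, n, K)
  for (i in seq_len(n)) {
    w <- numeric(K)
    for (u in seq_len(K)) {
      d2 <- 0
      for (l in seq_len(ncol(Z))) d2 <- d2 + (Z[i, l] - mu[u, l])^2
      w[u] <- 1 / (1 + d2)
    }
    Q[i, ] <- w / sum(w)
  }
  Q
}

oracle_target <- function(Q) {
  n <- nrow(Q); K <- ncol(Q)
  f <- numeric(K)
  for (u in seq_len(K)) for (i in seq_len(n)) f[u] <- f[u] + Q[i, u]
  P <- matrix(0, n, K)
  for (i in seq_len(n)) {
    w <- numeric(K)
    for (u in seq_len(K)) w[u] <- Q[i, u]^2 / f[u]
    P[i, ] <- w / sum(w)
  }
  P
}

oracle_nmi <- function(l, lG) {
  ul <- unique(l); ug <- unique(lG); n <- length(l)
  mi <- 0
  for (a in ul) for (b in ug) {
    nij <- sum(l == a & lG == b)
    if (nij > 0)
      mi <- mi + (nij / n) * log(nij * n / (sum(l == a) * sum(lG == b)))
  }
  ha <- 0; hb <- 0
  for (a in ul) { p <- sum(l == a) / n; ha <- ha - p * log(p) }
  for (b in ug) { p <- sum(lG == b) / n; hb <- hb - p * log(p) }
  if (ha == 0 || hb == 0) return(as.numeric(mi == 0 && ha == hb))
  mi / sqrt(ha * hb)
}

# ARI by brute-force counting over all unordered pairs
oracle_ari_pairs <- function(l, lG) {
  n <- length(l)
  ss <- sd <- ds <- dd <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_l <- l[i] == l[j]; same_g <- lG[i] == lG[j]
    if (same_l && same_g) ss <- ss + 1
    else if (same_l && !same_g) sd <- sd + 1
    else if (!same_l && same_g) ds <- ds + 1
    else dd <- dd + 1
  }
  tot <- ss + sd + ds + dd
  exp_ss <- (ss + sd) * (ss + ds) / tot
  max_ss <- ((ss + sd) + (ss + ds)) / 2
  if (max_ss == exp_ss) return(1)
  (ss - exp_ss) / (max_ss - exp_ss)
}

oracle_v_measure <- function(l, lG) {
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  cond_ent <- function(a, b) {   # H(a | b)
    h <- 0; n <- length(a)
    for (v in unique(b)) {
      idx <- b == v
      p <- table(a[idx]) / sum(idx)
      h <- h - sum(idx) / n * sum(p * log(p))
    }
    h
  }
  hC <- ent(lG); hK <- ent(l)
  h <- if (hC == 0) 1 else 1 - cond_ent(lG, l) / hC
  cc <- if (hK == 0) 1 else 1 - cond_ent(l, lG) / hK
  if (h + cc == 0) return(0)
  2 * h * cc / (h + cc)
}

random_labels <- function(n, K) sample(seq_len(K), n, replace = TRUE)

# small preprocessed dataset + graph shared by several tests
tiny_pipeline_input <- function(seed = 5, n = 40, g = 60, K = 3, d = 30) {
  sim <- simulate_counts(n = n, g = g, K = K, separation = 8,
                         dropout_strength = 0.2, seed = seed)
  Xn <- preprocess_counts(sim$counts, d = d)
  list(sim = sim, Xn = Xn, graph = build_cell_graph(Xn, k = 8))
}

oracle_asw <- function(X, labels) {
  n <- nrow(X)
  s <- numeric(n)
  dist_ij <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, dist_ij, numeric(1), i = i))
    b <- Inf
    for (u in setdiff(unique(labels), labels[i])) {
      oth <- which(labels == u)
      b <- min(b, mean(vapply(oth, dist_ij, numeric(1), i = i)))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

oracle_dbi <- function(X, labels) {
  ul <- sort(unique(labels))
  Kn <- length(ul)
  cent <- list(); S <- numeric(Kn)
  for (i in seq_len(Kn)) {
    pts <- X[labels == ul[i], , drop = FALSE]
    cent[[i]] <- colMeans(pts)
    S[i] <- mean(apply(pts, 1, function(p) sqrt(sum((p - cent[[i]])^2))))
  }
  out <- 0
  for (i in seq_len(Kn)) {
    best <- -Inf
    for (j in seq_len(Kn)) {
      if (i == j) next
      E <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (S[i] + S[j]) / E)
    }
    out <- out + best
  }
  out / Kn
}

# default pipeline settings used for the frozen fixture golden files
fixture_fit <- function() {
  sim <- worked_fixture()
  suppressWarnings(scgcae(sim$counts, K = 3, d = 80, k = 10,
                          cfg = train_config(pretrain_epochs = 100,
                                             max_iters = 30, seed = 1)))
}
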