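#' Loss weights for the joint objective
#'
#' `L = gamma1 * L_r + gamma2 * L_m + gamma3 * L_c`: graph
#' reconstruction, expression reconstruction and clustering. All three
#' components are averaged per cell / per entry inside the training loop,
#' so the weights do not depend on dataset size.
#'
#' @param gamma1,gamma2,gamma3 positive weights (defaults 0.1, 1, 0.5).
#' @return `scg_weights` list.
#' @export
loss_weights <- function(gamma1 = 0.1, gamma2 = 1, gamma3 = 0.5) {
  if (any(c(gamma1, gamma2, gamma3) < 0) || gamma2 <= 0)
    stop("loss weights must be nonnegative (gamma2 > 0)")
  structure(list(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3),
            class = "scg_weights")
}

#' Training configuration
#'
#' @param lr learning rate (default 5e-4 under Adam).
#' @param pretrain_epochs autoencoder-only epochs before center
#'   initialization (default 400).
#' @param max_iters joint optimization iterations (default 300); the
#'   stopping rule is reaching this count.
#' @param target_update_interval iterations between refreshes of the
#'   target distribution P (default 10).
#' @param batch_threshold cells per shard in batched mode (default 25000).
#' @param optimizer `"adam"` (default) or `"sgd"` (the literal
#'   gradient-descent updates, including the center update rule).
#' @param init_strategy center initialization, see [init_centers()].
#' @param seed integer seed governing weight init, k-means and sharding.
#' @return `scg_config` list.
#' @export
train_config <- function(lr = 5e-4, pretrain_epochs = 400L,
                         max_iters = 300L, target_update_interval = 10L,
                         batch_threshold = 25000L,
                         optimizer = c("adam", "sgd"),
                         init_strategy = c("auto", "kmeans", "spectral"),
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  init_strategy <- match.arg(init_strategy)
  if (lr <= 0) stop("lr must be positive")
  if (max_iters < 0L || pretrain_epochs < 0L) stop("negative iteration count")
  if (batch_threshold < 1L) stop("batch_threshold must be >= 1")
  structure(list(lr = lr, pretrain_epochs = as.integer(pretrain_epochs),
                 max_iters = as.integer(max_iters),
                 target_update_interval = as.integer(target_update_interval),
                 batch_threshold = as.integer(batch_threshold),
                 optimizer = optimizer, init_strategy = init_strategy,
                 seed = as.integer(seed)),
            class = "scg_config")
}

#' Weighted total loss
#'
#' @param Lr,Lm,Lc loss components.
#' @param w `scg_weights` object.
#' @return `gamma1*Lr + gamma2*Lm + gamma3*Lc`.
#' @export
total_loss <- function(Lr, Lm, Lc, w = loss_weights()) {
  w$gamma1 * Lr + w$gamma2 * Lm + w$gamma3 * Lc
}

#' Closed-form gradients of the clustering loss
#'
#' For the Student-t soft assignment and fixed target P:
#' `dL_c/dz_i =  2 sum_u (1 + ||z_i - mu_u||^2)^{-1} (p_iu - q_iu)(z_i - mu_u)`
#' `dL_c/dmu_u = -2 sum_i (1 + ||z_i - mu_u||^2)^{-1} (p_iu - q_iu)(z_i - mu_u)`
#'
#' @param Z embedding (n x z_dim).
#' @param mu centers (K x z_dim).
#' @param P target distribution (n x K).
#' @param Q soft assignment (n x K).
#' @return List with `dZ` (n x z_dim) and `dmu` (K x z_dim).
#' @export
cluster_gradients <- function(Z, mu, P, Q) {
  Z <- as.matrix(Z); mu <- as.matrix(mu)
  W <- 2 * (P - Q) / (1 + squared_distances(Z, mu))   # n x K kernel
  # dZ_i = sum_u W_iu (z_i - mu_u);  dmu_u = -sum_i W_iu (z_i - mu_u)
  dZ <- rowSums(W) * Z - W %*% mu
  dmu <- -(crossprod(W, Z) - colSums(W) * mu)
  list(dZ = dZ, dmu = dmu)
}

#' Gradient-descent update of the cluster centers
#'
#' `mu_u <- mu_u - (lr / n) * dL_c/dmu_u`.
#'
#' @param mu centers (K x z_dim).
#' @param dmu gradient from [cluster_gradients()].
#' @param lr learning rate.
#' @param n number of cells.
#' @return Updated center matrix.
#' @export
update_centers <- function(mu, dmu, lr, n) {
  if (lr < 0) stop("lr must be nonnegative")
  mu - (lr / n) * dmu
}

#' Fit the graph autoencoder and self-optimizing clustering
#'
#' Three phases: (1) pretrain encoder and decoders on the weighted graph
#' + expression reconstruction losses; (2) initialize cluster centers on
#' the pretrained embedding; (3) jointly minimize all three losses,
#' refreshing the target distribution every
#' `target_update_interval` iterations until `max_iters`. Reproducible
#' under a fixed seed.
#'
#' @param Xhat `scg_norm` object or numeric matrix (n x d).
#' @param graph `scg_graph` object from [build_cell_graph()].
#' @param K number of clusters.
#' @param w `scg_weights` object.
#' @param cfg `scg_config` object.
#' @param decoder `"multinomial"` (default) or `"zinb"` (ablation).
#' @param params optional pre-initialized `scg_params` (e.g. a warm
#'   start); default fresh Glorot initialization from `cfg$seed`.
#' @return `scg_fit` list: `labels`, `Z`, `Q`, `P`, `centers`, `params`,
#'   `history` (per-iteration component losses), `init`, `cell_ids`.
#' @export
fit_scgcae <- function(Xhat, graph, K, w = loss_weights(),
                       cfg = train_config(), decoder = "multinomial",
                       params = NULL) {
  V <- if (inherits(Xhat, "scg_norm")) Xhat$values else as.matrix(Xhat)
  cell_ids <- if (inherits(Xhat, "scg_norm")) Xhat$cell_ids else rownames(Xhat)
  if (!inherits(graph, "scg_graph")) stop("graph must be an scg_graph")
  n <- nrow(V); d <- ncol(V)
  if (nrow(graph$Abar) != n) stop("graph and Xhat disagree on cell count")
  if (K > n) stop("K exceeds number of cells")

  params <- if (is.null(params))
    gae_init(d, decoder = decoder, seed = cfg$seed) else params
  Abar <- graph$Abar
  A_target <- graph$A
  AX <- Abar %*% V
  opt <- adam_init(params)
  theta <- attr(params, "theta")
  is_zinb <- identical(attr(params, "decoder"), "zinb")

  history <- list()
  record <- function(phase, it, Lr, Lm, Lc) {
    history[[length(history) + 1L]] <<-
      data.frame(phase = phase, iter = it, graph = Lr, expr = Lm,
                 clust = Lc, total = total_loss(Lr, Lm, Lc, w))
  }
  comp_losses <- function(fw) {
    Lr <- graph_loss(A_target, sigmoid(tcrossprod(fw$Z)))
    Lm <- if (is_zinb) zinb_loss(V, fw$mu, fw$pi, theta)
          else multinomial_loss(V, fw$M)
    list(Lr = Lr, Lm = Lm)
  }

  # ---- phase 1: autoencoder pretraining ----
  for (ep in seq_len(cfg$pretrain_epochs)) {
    fw <- gae_forward(params, Abar, V, AX)
    grads <- gae_backward(params, fw, Abar, V, A_target, AX,
                          w$gamma1, w$gamma2)
    if (cfg$optimizer == "adam") {
      st <- adam_step(params, grads, opt, lr = cfg$lr)
      params <- st$params; opt <- st$state
    } else {
      for (nm in names(grads))
        params[[nm]] <- params[[nm]] - cfg$lr * grads[[nm]]
    }
    if (ep %% 10L == 0L || ep == cfg$pretrain_epochs) {
      ls <- comp_losses(fw)
      if (!is.finite(ls$Lr + ls$Lm))
        stop(sprintf("divergence (non-finite loss) at pretrain epoch %d", ep))
      record("pretrain", ep, ls$Lr, ls$Lm, 0)
    }
  }

  # ---- phase 2: center initialization ----
  fw <- gae_forward(params, Abar, V, AX)
  init <- init_centers(fw$Z, K, strategy = cfg$init_strategy,
                       graph = graph, seed = cfg$seed)
  mu <- init$centers
  opt_mu <- list(m = mu * 0, v = mu * 0, t = 0L)
  Q <- soft_assign(fw$Z, mu)
  P <- target_distribution(Q)

  # ---- phase 3: joint optimization ----
  for (it in seq_len(cfg$max_iters)) {
    fw <- gae_forward(params, Abar, V, AX)
    Q <- soft_assign(fw$Z, mu)
    if (it %% cfg$target_update_interval == 1L || cfg$target_update_interval == 1L)
      P <- target_distribution(Q)
    cg <- cluster_gradients(fw$Z, mu, P, Q)
    grads <- gae_backward(params, fw, Abar, V, A_target, AX,
                          w$gamma1, w$gamma2,
                          dZ_extra = (w$gamma3 / n) * cg$dZ)
    if (cfg$optimizer == "adam") {
      st <- adam_step(params, grads, opt, lr = cfg$lr)
      params <- st$params; opt <- st$state
      gmu <- (w$gamma3 / n) * cg$dmu
      opt_mu$t <- opt_mu$t + 1L
      opt_mu$m <- 0.9 * opt_mu$m + 0.1 * gmu
      opt_mu$v <- 0.999 * opt_mu$v + 0.001 * gmu^2
      mu <- mu - cfg$lr * (opt_mu$m / (1 - 0.9^opt_mu$t)) /
        (sqrt(opt_mu$v / (1 - 0.999^opt_mu$t)) + 1e-8)
    } else {
      for (nm in names(grads))
        params[[nm]] <- params[[nm]] - cfg$lr * grads[[nm]]
      mu <- update_centers(mu, w$gamma3 * cg$dmu, cfg$lr, n)
    }
    ls <- comp_losses(fw)
    Lc <- clustering_loss(P, Q) / n
    if (!is.finite(ls$Lr + ls$Lm + Lc))
      stop(sprintf("divergence (non-finite loss) at joint iteration %d", it))
    record("joint", it, ls$Lr, ls$Lm, Lc)
  }

  fw <- gae_forward(params, Abar, V, AX)
  Q <- soft_assign(fw$Z, mu)
  labels <- hard_labels(Q)
  structure(list(labels = labels, Z = fw$Z, Q = Q,
                 P = target_distribution(Q), centers = mu,
                 params = params, history = do.call(rbind, history),
                 init = init, cell_ids = cell_ids,
                 weights = w, config = cfg),
            class = "scg_fit")
}

#' @export
print.scg_fit <- function(x, ...) {
  cat(sprintf("<scg_fit> %d cells, %d clusters (init: %s)\n",
              length(x$labels), nrow(x$centers), x$init$strategy))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Batched fitting for large datasets
#'
#' Cells are randomly partitioned into shards of at most
#' `cfg$batch_threshold`; a cell-PPMI graph is built per shard while
#' network weights and cluster centers are shared across shards:
#' pretraining and joint optimization sweep the shards in turn, the
#' target distribution is refreshed per shard pass, and final labels are
#' assembled over all cells. With `n <= batch_threshold` this delegates
#' to [fit_scgcae()] and is identical to it under the same seed. A shard
#' smaller than K is merged with its neighbour.
#'
#' @param Xhat `scg_norm` object or numeric matrix.
#' @param K number of clusters.
#' @param w `scg_weights` object.
#' @param cfg `scg_config` object.
#' @param k,steps,alpha,graph_type graph construction settings per shard
#'   (see [build_cell_graph()]).
#' @param decoder `"multinomial"` or `"zinb"`.
#' @return `scg_fit` list (with `shards` recording the partition).
#' @export
fit_batched <- function(Xhat, K, w = loss_weights(), cfg = train_config(),
                        k = 15L, steps = 2L, alpha = 0.98,
                        graph_type = "ppmi", decoder = "multinomial") {
  V <- if (inherits(Xhat, "scg_norm")) Xhat$values else as.matrix(Xhat)
  cell_ids <- if (inherits(Xhat, "scg_norm")) Xhat$cell_ids else rownames(V)
  n <- nrow(V)
  if (n <= cfg$batch_threshold) {
    graph <- build_cell_graph(V, k = k, steps = steps, alpha = alpha,
                              graph_type = graph_type)
    res <- fit_scgcae(Xhat, graph, K, w, cfg, decoder = decoder)
    res$shards <- rep(1L, n)
    return(res)
  }
  set.seed(cfg$seed)
  n_shards <- ceiling(n / cfg$batch_threshold)
  shard <- sample(rep(seq_len(n_shards), length.out = n))
  # merge shards smaller than K into the previous shard
  repeat {
    sizes <- tabulate(shard, n_shards)
    small <- which(sizes > 0 & sizes < K)
    if (length(small) == 0L) break
    tgt <- if (small[1L] > 1L) small[1L] - 1L else small[1L] + 1L
    shard[shard == small[1L]] <- tgt
  }
  shard <- as.integer(factor(shard))
  n_shards <- max(shard)
  idx <- split(seq_len(n), shard)
  graphs <- lapply(idx, function(i)
    build_cell_graph(V[i, , drop = FALSE], k = min(k, length(i)),
                     steps = steps, alpha = alpha,
                     graph_type = graph_type))
  AXs <- lapply(seq_len(n_shards), function(s)
    graphs[[s]]$Abar %*% V[idx[[s]], , drop = FALSE])

  params <- gae_init(ncol(V), decoder = decoder, seed = cfg$seed)
  opt <- adam_init(params)
  theta <- attr(params, "theta")
  is_zinb <- identical(attr(params, "decoder"), "zinb")
  step_params <- function(grads) {
    if (cfg$optimizer == "adam") {
      st <- adam_step(params, grads, opt, lr = cfg$lr)
      params <<- st$params; opt <<- st$state
    } else {
      for (nm in names(grads))
        params[[nm]] <<- params[[nm]] - cfg$lr * grads[[nm]]
    }
  }

  for (ep in seq_len(cfg$pretrain_epochs)) {
    for (s in seq_len(n_shards)) {
      Vs <- V[idx[[s]], , drop = FALSE]
      fw <- gae_forward(params, graphs[[s]]$Abar, Vs, AXs[[s]])
      step_params(gae_backward(params, fw, graphs[[s]]$Abar, Vs,
                               graphs[[s]]$A, AXs[[s]],
                               w$gamma1, w$gamma2))
    }
  }

  encode_all <- function() {
    Z <- matrix(0, n, attr(params, "z_dim"))
    for (s in seq_len(n_shards))
      Z[idx[[s]], ] <- gae_forward(params, graphs[[s]]$Abar,
                                   V[idx[[s]], , drop = FALSE],
                                   AXs[[s]])$Z
    Z
  }
  Z <- encode_all()
  init <- init_centers(Z, K, strategy = if (cfg$init_strategy == "auto")
    "kmeans" else cfg$init_strategy,
    graph = if (cfg$init_strategy == "spectral") graphs[[1L]] else NULL,
    seed = cfg$seed)
  mu <- init$centers

  for (it in seq_len(cfg$max_iters)) {
    for (s in seq_len(n_shards)) {
      Vs <- V[idx[[s]], , drop = FALSE]
      ns <- length(idx[[s]])
      fw <- gae_forward(params, graphs[[s]]$Abar, Vs, AXs[[s]])
      Q <- soft_assign(fw$Z, mu)
      P <- target_distribution(Q)
      cg <- cluster_gradients(fw$Z, mu, P, Q)
      step_params(gae_backward(params, fw, graphs[[s]]$Abar, Vs,
                               graphs[[s]]$A, AXs[[s]],
                               w$gamma1, w$gamma2,
                               dZ_extra = (w$gamma3 / ns) * cg$dZ))
      mu <- update_centers(mu, w$gamma3 * cg$dmu, cfg$lr, ns)
    }
  }

  Z <- encode_all()
  Q <- soft_assign(Z, mu)
  labels <- hard_labels(Q)
  structure(list(labels = labels, Z = Z, Q = Q,
                 P = target_distribution(Q), centers = mu,
                 params = params, history = NULL, init = init,
                 cell_ids = cell_ids, weights = w, config = cfg,
                 shards = shard),
            class = "scg_fit")
}

#' End-to-end pipeline on a raw count matrix
#'
#' Preprocess (filter, normalize, HVG-select), build the cell-PPMI
#' graph, fit the graph autoencoder with self-optimizing clustering, and
#' return labels plus everything needed downstream. Delegates to
#' [fit_batched()] when the dataset exceeds `cfg$batch_threshold` cells.
#'
#' @param X `scg_counts` object or raw count matrix (cells x genes).
#' @param K number of clusters (required, as in the underlying method).
#' @param d number of highly variable genes (default 500).
#' @param k,steps,alpha,graph_type cell-graph settings
#'   (see [build_cell_graph()]).
#' @param w,cfg loss weights and training configuration.
#' @param decoder `"multinomial"` or `"zinb"`.
#' @return `scg_fit` with an added `norm` element (the `scg_norm` input
#'   to the model, for interpretation and reporting).
#' @export
scgcae <- function(X, K, d = 500L, k = 15L, steps = 2L, alpha = 0.98,
                   graph_type = "ppmi", w = loss_weights(),
                   cfg = train_config(), decoder = "multinomial") {
  Xn <- preprocess_counts(X, d = d)
  if (nrow(Xn$values) > cfg$batch_threshold) {
    res <- fit_batched(Xn, K, w, cfg, k = k, steps = steps, alpha = alpha,
                       graph_type = graph_type, decoder = decoder)
  } else {
    graph <- build_cell_graph(Xn, k = k, steps = steps, alpha = alpha,
                              graph_type = graph_type)
    res <- fit_scgcae(Xn, graph, K, w, cfg, decoder = decoder)
    res$graph <- graph
  }
  res$norm <- Xn
  res
}
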