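#' Initialize graph-autoencoder parameters
#'
#' Glorot-uniform weights for the two GCN encoder layers
#' (d -> h1 -> z_dim), the three fully connected decoder hidden layers
#' (z_dim -> 128 -> 256 -> 512) and the output head mapping back to the
#' d genes. The multinomial head is a single weight matrix (softmax
#' output); the ZINB ablation decoder adds a dropout-probability head and
#' uses a fixed dispersion.
#'
#' @param d number of genes in the normalized matrix.
#' @param h1 first GCN layer width (default 128).
#' @param z_dim embedding dimension (default 15).
#' @param hidden decoder hidden widths (default `c(128, 256, 512)`).
#' @param decoder `"multinomial"` (default) or `"zinb"`.
#' @param theta fixed ZINB dispersion (ignored for multinomial).
#' @param seed integer seed for weight initialization.
#' @return `scg_params` list of weight matrices and bias vectors.
#' @export
gae_init <- function(d, h1 = 128L, z_dim = 15L, hidden = c(128L, 256L, 512L),
                     decoder = c("multinomial", "zinb"), theta = 10,
                     seed = 1L) {
  decoder <- match.arg(decoder)
  set.seed(seed)
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  p <- list(W1 = glorot(d, h1), W2 = glorot(h1, z_dim))
  widths <- c(z_dim, hidden)
  for (l in seq_along(hidden)) {
    p[[paste0("Wd", l)]] <- glorot(widths[l], widths[l + 1L])
    p[[paste0("bd", l)]] <- numeric(widths[l + 1L])
  }
  p$Wm <- glorot(hidden[length(hidden)], d)
  if (decoder == "zinb") p$Wpi <- glorot(hidden[length(hidden)], d)
  structure(p, class = "scg_params", decoder = decoder, theta = theta,
            h1 = as.integer(h1), z_dim = as.integer(z_dim),
            hidden = as.integer(hidden), d = as.integer(d))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Two-layer graph convolutional encoder
#'
#' `Z = relu(Abar relu(Abar Xhat W1) W2)`: each layer mixes every cell
#' with its graph neighbourhood (multiplication by the normalized
#' affinity `Abar`) before the linear map and ReLU. The embedding is
#' entrywise nonnegative by construction.
#'
#' @param Xhat `scg_norm` object or numeric matrix (n x d).
#' @param Abar `scg_graph` object or numeric matrix (n x n).
#' @param params `scg_params` from [gae_init()].
#' @return Embedding matrix Z (n x z_dim).
#' @export
gcn_encode <- function(Xhat, Abar, params) {
  V <- if (inherits(Xhat, "scg_norm")) Xhat$values else as.matrix(Xhat)
  G <- if (inherits(Abar, "scg_graph")) Abar$Abar else as.matrix(Abar)
  if (nrow(G) != nrow(V)) stop("Abar and Xhat disagree on cell count")
  if (ncol(V) != nrow(params$W1)) stop("Xhat and W1 disagree on gene count")
  H <- relu(G %*% (V %*% params$W1))
  relu(G %*% (H %*% params$W2))
}

#' Inner-product graph decoder
#'
#' Reconstructs the cell graph as the sigmoid of the cell Gram matrix,
#' `Ahat_ij = sigmoid(<z_i, z_j>)`. Symmetric with entries in (0, 1).
#'
#' @param Z embedding matrix (n x z_dim).
#' @return Reconstructed affinity matrix (n x n).
#' @export
decode_graph <- function(Z) {
  Z <- as.matrix(Z)
  if (any(!is.finite(Z))) stop("Z must be finite")
  sigmoid(tcrossprod(Z))
}

#' Mean squared graph-reconstruction loss
#'
#' `L_r = (1/n^2) sum_ij (A_ij - Ahat_ij)^2`.
#'
#' @param A target affinity (`scg_ppmi`, `scg_graph` or matrix).
#' @param Ahat reconstructed affinity (n x n).
#' @return Scalar loss.
#' @export
graph_loss <- function(A, Ahat) {
  M <- if (inherits(A, "scg_ppmi") || inherits(A, "scg_graph")) A$A
       else as.matrix(A)
  Ahat <- as.matrix(Ahat)
  if (!all(dim(M) == dim(Ahat))) stop("A and Ahat shapes differ")
  mean((M - Ahat)^2)
}

#' Multinomial expression decoder
#'
#' Three ReLU dense layers (128, 256, 512 units) map the embedding to
#' per-gene logits; a per-cell softmax yields gene proportions `M`, each
#' row summing to 1.
#'
#' @param Z embedding matrix (n x z_dim).
#' @param params `scg_params` from [gae_init()].
#' @return `scg_multinom` list: `M` (n x d row-stochastic),
#'   `cell_totals` (set by [multinomial_loss()] callers as needed).
#' @export
decode_multinomial <- function(Z, params) {
  fw <- decoder_forward(as.matrix(Z), params)
  structure(list(M = fw$M), class = "scg_multinom")
}

# decoder forward pass returning all activations (needed for backprop)
decoder_forward <- function(Z, params) {
  H1 <- relu(sweep(Z %*% params$Wd1, 2L, params$bd1, "+"))
  H2 <- relu(sweep(H1 %*% params$Wd2, 2L, params$bd2, "+"))
  H3 <- relu(sweep(H2 %*% params$Wd3, 2L, params$bd3, "+"))
  logits <- H3 %*% params$Wm
  out <- list(H1 = H1, H2 = H2, H3 = H3, logits = logits,
              M = row_softmax(logits))
  if (identical(attr(params, "decoder"), "zinb")) {
    out$mu <- exp(pmin(pmax(logits, -12), 12))
    out$pi <- sigmoid(H3 %*% params$Wpi)
  }
  out
}

row_softmax <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Multinomial negative log-likelihood loss
#'
#' `L_m = -(1/n) sum_ij Xhat_ij ln m_ij`: the multinomial NLL with the
#' data-only constant dropped, averaged per cell so the loss weight does
#' not scale with dataset size.
#'
#' @param Xhat `scg_norm` object or numeric matrix (n x d).
#' @param M `scg_multinom` object or row-stochastic matrix (n x d).
#' @return Scalar loss.
#' @export
multinomial_loss <- function(Xhat, M) {
  V <- if (inherits(Xhat, "scg_norm")) Xhat$values else as.matrix(Xhat)
  P <- if (inherits(M, "scg_multinom")) M$M else as.matrix(M)
  if (!all(dim(V) == dim(P))) stop("Xhat and M shapes differ")
  if (any(P <= 0 & V > 0)) stop("m_ij <= 0 where Xhat_ij > 0")
  idx <- V > 0
  -sum(V[idx] * log(P[idx])) / nrow(V)
}

# ZINB negative log-likelihood with fixed dispersion theta, averaged per
# cell; evaluated on the continuous normalized values via lgamma
zinb_loss <- function(V, mu, pi, theta) {
  pi <- pmin(pmax(pi, 1e-8), 1 - 1e-8)
  mu <- pmax(mu, 1e-10)
  p0 <- (theta / (theta + mu))^theta
  nll <- matrix(0, nrow(V), ncol(V))
  z <- V <= 0
  nll[z] <- -log(pi[z] + (1 - pi[z]) * p0[z])
  x <- V[!z]; m <- mu[!z]
  nll[!z] <- -(log1p(-pi[!z]) +
               lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
               theta * log(theta / (theta + m)) + x * log(m / (theta + m)))
  sum(nll) / nrow(V)
}

# full forward pass of the autoencoder; AX = Abar %*% Xhat may be
# precomputed by the training loop (Abar and Xhat are fixed)
gae_forward <- function(params, Abar, Xhat, AX = NULL) {
  if (is.null(AX)) AX <- Abar %*% Xhat
  E1pre <- AX %*% params$W1
  E1 <- relu(E1pre)
  AE1 <- Abar %*% E1
  Zpre <- AE1 %*% params$W2
  Z <- relu(Zpre)
  dec <- decoder_forward(Z, params)
  c(list(E1pre = E1pre, E1 = E1, AE1 = AE1, Zpre = Zpre, Z = Z), dec)
}

# Backward pass: gradients of
#   gamma1 * L_r + gamma2 * L_m(+zinb) [+ extra dL/dZ, e.g. clustering]
# with respect to every parameter. `fw` is the gae_forward cache.
# Returns a list of gradients named like the parameters.
gae_backward <- function(params, fw, Abar, Xhat, A_target, AX,
                         gamma1, gamma2, dZ_extra = NULL) {
  n <- nrow(fw$Z)
  grads <- list()

  # expression decoder head
  if (identical(attr(params, "decoder"), "zinb")) {
    theta <- attr(params, "theta")
    pi <- pmin(pmax(fw$pi, 1e-8), 1 - 1e-8)
    mu <- pmax(fw$mu, 1e-10)
    p0 <- (theta / (theta + mu))^theta
    z <- Xhat <= 0
    dmu <- matrix(0, n, ncol(Xhat))
    dpi <- matrix(0, n, ncol(Xhat))
    denom <- pi + (1 - pi) * p0
    dmu[z] <- ((1 - pi[z]) * p0[z] * theta / (theta + mu[z])) / denom[z]
    dpi[z] <- -(1 - p0[z]) / denom[z]
    dmu[!z] <- (Xhat[!z] + theta) / (theta + mu[!z]) - Xhat[!z] / mu[!z]
    dpi[!z] <- 1 / (1 - pi[!z])
    # through mu = exp(clipped logits) and pi = sigmoid(.)
    dlogits <- (gamma2 / n) * dmu * mu *
      (fw$logits > -12 & fw$logits < 12)
    dpilog <- (gamma2 / n) * dpi * pi * (1 - pi)
    grads$Wm <- crossprod(fw$H3, dlogits)
    grads$Wpi <- crossprod(fw$H3, dpilog)
    dH3 <- tcrossprod(dlogits, params$Wm) +
           tcrossprod(dpilog, params$Wpi)
  } else {
    # d L_m / d logits = (rowsum(Xhat) * M - Xhat) / n
    ni <- rowSums(Xhat)
    dlogits <- (gamma2 / n) * (ni * fw$M - Xhat)
    grads$Wm <- crossprod(fw$H3, dlogits)
    dH3 <- dlogits %*% t(params$Wm)
  }

  dH3 <- dH3 * (fw$H3 > 0)
  grads$Wd3 <- crossprod(fw$H2, dH3)
  grads$bd3 <- colSums(dH3)
  dH2 <- (dH3 %*% t(params$Wd3)) * (fw$H2 > 0)
  grads$Wd2 <- crossprod(fw$H1, dH2)
  grads$bd2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(params$Wd2)) * (fw$H1 > 0)
  grads$Wd1 <- crossprod(fw$Z, dH1)
  grads$bd1 <- colSums(dH1)
  dZ <- dH1 %*% t(params$Wd1)

  # graph decoder: L_r = mean((A - sigmoid(Z Z^T))^2)
  if (gamma1 != 0) {
    G <- tcrossprod(fw$Z)
    Ahat <- sigmoid(G)
    dG <- gamma1 * (2 / n^2) * (Ahat - A_target) * Ahat * (1 - Ahat)
    dZ <- dZ + (dG + t(dG)) %*% fw$Z
  }

  if (!is.null(dZ_extra)) dZ <- dZ + dZ_extra

  # encoder
  dZpre <- dZ * (fw$Zpre > 0)
  grads$W2 <- crossprod(fw$AE1, dZpre)
  dE1 <- (crossprod(Abar, dZpre)) %*% t(params$W2) * (fw$E1pre > 0)
  grads$W1 <- crossprod(AX, dE1)
  grads
}

# Adam optimizer state and update (hand-rolled; operates on the named
# gradient list returned by gae_backward)
adam_init <- function(params) {
  nm <- names(params)
  list(m = stats::setNames(lapply(params, function(p) p * 0), nm),
       v = stats::setNames(lapply(params, function(p) p * 0), nm),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
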