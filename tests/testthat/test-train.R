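test_that("total loss is the weighted sum, linear in each weight", {
  expect_equal(total_loss(1, 2, 3, loss_weights(1, 1, 1)), 6)
  expect_equal(total_loss(1, 2, 3, loss_weights(0.5, 2, 0)), 4.5)
  # gamma3 = 0 reduces to the pure autoencoder objective
  w0 <- loss_weights(0.3, 1.2, 0)
  expect_equal(total_loss(5, 7, 100, w0), 0.3 * 5 + 1.2 * 7)
  expect_error(loss_weights(-1, 1, 1))
})

test_that("clustering-loss gradients match finite differences and vanish at P = Q", {
  set.seed(20)
  Z <- matrix(rnorm(8 * 3), 8, 3)
  mu <- matrix(rnorm(3 * 3), 3, 3)
  Q <- soft_assign(Z, mu)
  # P = Q: both gradients vanish
  g0 <- cluster_gradients(Z, mu, Q, Q)
  expect_lt(max(abs(g0$dZ)), 1e-12)
  expect_lt(max(abs(g0$dmu)), 1e-12)
  # z = mu single pair: zero gradient regardless of p, q
  g1 <- cluster_gradients(matrix(1:3, 1), matrix(1:3, 1),
                          matrix(1), matrix(1))
  expect_equal(g1$dZ, matrix(0, 1, 3))
  # finite differences of the KL loss with P frozen
  P <- target_distribution(Q)
  cg <- cluster_gradients(Z, mu, P, Q)
  f <- function(Z, mu) clustering_loss(P, soft_assign(Z, mu))
  eps <- 1e-6
  for (i in sample(length(Z), 6)) {
    Zp <- Z; Zp[i] <- Z[i] + eps
    Zm <- Z; Zm[i] <- Z[i] - eps
    fd <- (f(Zp, mu) - f(Zm, mu)) / (2 * eps)
    expect_lt(abs(fd - cg$dZ[i]) / max(1e-8, abs(fd) + abs(cg$dZ[i])), 1e-4)
  }
  for (i in sample(length(mu), 6)) {
    mp <- mu; mp[i] <- mu[i] + eps
    mm <- mu; mm[i] <- mu[i] - eps
    fd <- (f(Z, mp) - f(Z, mm)) / (2 * eps)
    expect_lt(abs(fd - cg$dmu[i]) / max(1e-8, abs(fd) + abs(cg$dmu[i])), 1e-4)
  }
})

test_that("center update performs the literal gradient step", {
  mu <- matrix(c(1, 2), 1, 2)
  dmu <- matrix(c(10, -20), 1, 2)
  # hand arithmetic: mu - (0.5/4) * dmu
  expect_equal(update_centers(mu, dmu, lr = 0.5, n = 4),
               matrix(c(1 - 1.25, 2 + 2.5), 1, 2))
  expect_equal(update_centers(mu, 0 * dmu, 0.5, 4), mu)
  expect_equal(update_centers(mu, dmu, 0, 4), mu)
})

test_that("fit recovers well-separated synthetic clusters and is deterministic", {
  sim <- simulate_counts(n = 120, g = 120, K = 4, separation = 8,
                         dropout_strength = 0.2, seed = 23)
  Xn <- preprocess_counts(sim$counts, d = 80)
  graph <- build_cell_graph(Xn, k = 10)
  cfg <- train_config(pretrain_epochs = 150, max_iters = 40, seed = 4)
  fit1 <- suppressWarnings(fit_scgcae(Xn, graph, 4, cfg = cfg))
  expect_gte(ari(fit1$labels, sim$labels), 0.95)
  # same seed, same labels (end-to-end determinism)
  fit2 <- suppressWarnings(fit_scgcae(Xn, graph, 4, cfg = cfg))
  expect_identical(fit1$labels, fit2$labels)
  expect_equal(fit1$Z, fit2$Z, tolerance = 1e-12)
  # gamma3 = 0 with no joint iterations keeps the initialization labels
  cfg0 <- train_config(pretrain_epochs = 30, max_iters = 0, seed = 4)
  fit0 <- suppressWarnings(fit_scgcae(Xn, graph, 4, w = loss_weights(0.1, 1, 0),
                                      cfg = cfg0))
  expect_equal(hard_labels(soft_assign(fit0$Z, fit0$centers)),
               fit0$init$labels)
})

test_that("pretraining loss trends downward on a small instance", {
  inp <- tiny_pipeline_input(seed = 29, n = 40, g = 60, K = 2, d = 30)
  fit <- suppressWarnings(fit_scgcae(inp$Xn, inp$graph, 2,
             cfg = train_config(pretrain_epochs = 120, max_iters = 0,
                                seed = 1)))
  h <- fit$history[fit$history$phase == "pretrain", ]
  # averaged over recording windows: the back half is below the front half
  half <- nrow(h) %/% 2
  expect_lt(mean(h$total[(half + 1):nrow(h)]), mean(h$total[1:half]))
  # strict monotone trend allowing small SGD noise
  expect_lt(h$total[nrow(h)], h$total[1])
})

test_that("SGD mode runs the literal update rules without diverging", {
  inp <- tiny_pipeline_input(seed = 31, n = 30, g = 50, K = 2, d = 25)
  fit <- suppressWarnings(fit_scgcae(inp$Xn, inp$graph, 2,
             cfg = train_config(lr = 1e-4, pretrain_epochs = 30,
                                max_iters = 10, optimizer = "sgd",
                                seed = 2)))
  expect_true(all(is.finite(fit$history$total)))
  expect_length(fit$labels, 30)
})

test_that("batched fitting delegates below threshold and covers all cells above it", {
  sim <- simulate_counts(n = 90, g = 100, K = 3, separation = 8,
                         dropout_strength = 0.2, seed = 37)
  Xn <- preprocess_counts(sim$counts, d = 60)
  cfg_small <- train_config(pretrain_epochs = 60, max_iters = 20, seed = 5,
                            batch_threshold = 200L)
  # below threshold: identical to the plain fit under the same seed
  direct <- suppressWarnings({
    graph <- build_cell_graph(Xn, k = 10)
    fit_scgcae(Xn, graph, 3, cfg = cfg_small)
  })
  viafb <- suppressWarnings(fit_batched(Xn, 3, cfg = cfg_small, k = 10))
  expect_identical(direct$labels, viafb$labels)
  # above threshold: two shards, every cell labeled, clusters recovered
  cfg_sh <- train_config(pretrain_epochs = 80, max_iters = 20, seed = 5,
                         batch_threshold = 50L)
  fb <- suppressWarnings(fit_batched(Xn, 3, cfg = cfg_sh, k = 10))
  expect_length(fb$labels, 90)
  expect_equal(sort(unique(fb$shards)), c(1L, 2L))
  expect_gte(ari(fb$labels, sim$labels), 0.8)
})

test_that("divergence is reported with its iteration index", {
  inp <- tiny_pipeline_input(seed = 41, n = 25, g = 40, K = 2, d = 20)
  expect_error(
    suppressWarnings(fit_scgcae(inp$Xn, inp$graph, 2,
        cfg = train_config(lr = 1e6, pretrain_epochs = 40, max_iters = 0,
                           optimizer = "sgd", seed = 1))),
    "divergence|non-finite|missing")
})
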