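test_that("KNN graph links each cell to its k nearest, self included", {
  # k = 1: identity
  Z <- matrix(rnorm(20), 10, 2)
  K1 <- build_knn(Z, k = 1)
  expect_equal(K1$adjacency, diag(10))
  # 1-D cells at 0, 1, 10 with k = 2: brute-force neighbourhoods
  K2 <- build_knn(matrix(c(0, 1, 10), 3, 1), k = 2)
  expect_equal(K2$adjacency,
               matrix(c(1, 1, 0,
                        1, 1, 0,
                        0, 1, 1), 3, 3, byrow = TRUE))
  # every row sums to k; diagonal all ones even with duplicated cells
  Zd <- rbind(Z, Z[1:3, ])
  K3 <- build_knn(Zd, k = 4)
  expect_true(all(rowSums(K3$adjacency) == 4))
  expect_true(all(diag(K3$adjacency) == 1))
  expect_error(build_knn(Z, k = 11))
})

test_that("random surfing recursion conserves probability and matches one unrolled step", {
  set.seed(1)
  K <- build_knn(matrix(rnorm(24), 12, 2), k = 3)
  # rows of every P_s sum to 1 => rows of U sum to S
  for (S in c(1, 3, 5)) {
    U <- random_surf(K, steps = S, alpha = 0.7)$U
    expect_equal(rowSums(U), rep(S, 12), tolerance = 1e-12)
  }
  # S = 1 equals alpha*Ktilde + (1-alpha) I exactly
  Kt <- K$adjacency / rowSums(K$adjacency)
  U1 <- random_surf(K, steps = 1, alpha = 0.6)$U
  expect_equal(U1, 0.6 * Kt + 0.4 * diag(12), tolerance = 1e-14)
  # absorbing identity graph: U = S * I
  expect_equal(random_surf(diag(4), steps = 3, alpha = 0.9,
                           stochastic = FALSE)$U,
               3 * diag(4), tolerance = 1e-14)
  # hand-checked 2-node complete graph, alpha = 0.8, S = 2
  Kc <- matrix(0.5, 2, 2)
  U2 <- random_surf(Kc, steps = 2, alpha = 0.8, stochastic = FALSE)$U
  P1 <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2)
  P2 <- 0.8 * P1 %*% Kc + 0.2 * diag(2)
  expect_equal(U2, P1 + P2, tolerance = 1e-14)
})

test_that("closed-form surfing equals the recursion on random stochastic matrices", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    K <- matrix(runif(n * n), n, n)
    K <- K / rowSums(K)
    S <- sample(1:5, 1)
    alpha <- runif(1, 0.1, 1)
    Ur <- random_surf(K, steps = S, alpha = alpha, stochastic = FALSE,
                      method = "recursion")$U
    Uc <- random_surf(K, steps = S, alpha = alpha, stochastic = FALSE,
                      method = "closed_form")$U
    expect_lt(max(abs(Ur - Uc)), 1e-12)
  }
})

test_that("PPMI matches the entrywise definition and its invariances", {
  # constant U: independence, A = 0
  expect_equal(ppmi(matrix(2, 4, 4))$A, matrix(0, 4, 4))
  # hand-computed 2x2 (before symmetrization)
  U <- matrix(c(2, 0, 1, 1), 2, 2, byrow = TRUE)
  A <- ppmi(U, symmetrize = FALSE)$A
  expect_equal(A, matrix(c(log(4 / 3), 0, 0, log(2)), 2, 2, byrow = TRUE),
               tolerance = 1e-12)
  # loop oracle on random matrices; scale invariance; nonnegativity
  set.seed(7)
  for (rep in 1:10) {
    U <- matrix(rexp(20 * 20), 20, 20)
    U[sample(400, 60)] <- 0
    A1 <- ppmi(U, symmetrize = FALSE)$A
    expect_lt(max(abs(A1 - oracle_ppmi(U))), 1e-12)
    expect_true(all(A1 >= 0))
    A2 <- ppmi(7.3 * U, symmetrize = FALSE)$A
    expect_equal(A1, A2, tolerance = 1e-12)
  }
  # symmetrization
  As <- ppmi(U)$A
  expect_true(isSymmetric(As))
  expect_error(ppmi(matrix(0, 3, 3)), "zero total")
})

test_that("degree normalization follows D = diag((I+A)1)", {
  # A = 0: literal mode gives 0, renormalization gives I
  expect_equal(normalize_graph(matrix(0, 3, 3))$Abar, matrix(0, 3, 3))
  expect_equal(normalize_graph(matrix(0, 3, 3), renormalize = TRUE)$Abar,
               diag(3))
  # hand computation
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_graph(A)$Abar, matrix(c(0, .5, .5, 0), 2, 2))
  # symmetry preserved
  set.seed(2)
  S <- matrix(runif(25), 5, 5); S <- S + t(S)
  expect_true(isSymmetric(normalize_graph(S)$Abar))
})

test_that("PPMI affinity separates synthetic clusters", {
  inp <- tiny_pipeline_input(seed = 21, n = 60, g = 80, K = 2, d = 40)
  A <- inp$graph$A
  same <- outer(inp$sim$labels, inp$sim$labels, "==")
  diag(same) <- NA
  expect_gt(mean(A[which(same)]), mean(A[which(!same)]))
})
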