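test_that("GCN encoder matches the scalar-loop oracle and trivial cases", {
  set.seed(11)
  n <- 5; d <- 8; h1 <- 4; z <- 3
  for (rep in 1:10) {
    X <- matrix(rnorm(n * d), n, d)
    Abar <- matrix(runif(n * n), n, n); Abar <- (Abar + t(Abar)) / 2
    p <- gae_init(d, h1 = h1, z_dim = z, seed = rep)
    expect_lt(max(abs(gcn_encode(X, Abar, p) -
                      oracle_encode(X, Abar, p$W1, p$W2))), 1e-12)
  }
  # identity graph + identity-padded weights pass nonnegative X through
  p <- gae_init(d, h1 = h1, z_dim = z, seed = 1)
  p$W1 <- diag(1, d, h1); p$W2 <- diag(1, h1, z)
  X <- abs(matrix(rnorm(n * d), n, d))
  expect_equal(gcn_encode(X, diag(n), p), X[, 1:z], tolerance = 1e-14)
  # zero input gives zero embedding
  expect_equal(gcn_encode(matrix(0, n, d), diag(n), p), matrix(0, n, z))
  expect_error(gcn_encode(X[, 1:3], diag(n), p), "W1")
})

test_that("inner-product decoder is a symmetric sigmoid Gram matrix", {
  expect_equal(decode_graph(matrix(0, 4, 3)), matrix(0.5, 4, 4))
  Z <- rbind(c(1, 0), c(1, 0))
  expect_equal(decode_graph(Z)[1, 2], 1 / (1 + exp(-1)), tolerance = 1e-12)
  set.seed(2)
  Ah <- decode_graph(matrix(rnorm(18), 6, 3))
  expect_true(isSymmetric(Ah))
  expect_true(all(Ah > 0 & Ah < 1))
})

test_that("graph loss is the mean squared entrywise error", {
  A <- matrix(runif(16), 4, 4)
  expect_equal(graph_loss(A, A), 0)
  expect_equal(graph_loss(matrix(1), matrix(0.5)), 0.25)
  set.seed(3)
  Ah <- matrix(runif(16), 4, 4)
  oracle <- 0
  for (i in 1:4) for (j in 1:4) oracle <- oracle + (A[i, j] - Ah[i, j])^2
  expect_equal(graph_loss(A, Ah), oracle / 16, tolerance = 1e-14)
  expect_error(graph_loss(A, Ah[1:3, 1:3]), "shapes")
})

test_that("multinomial decoder rows are softmax proportions", {
  set.seed(4)
  d <- 12
  p <- gae_init(d, h1 = 4, z_dim = 3, hidden = c(4, 5, 6), seed = 4)
  Z <- abs(matrix(rnorm(6 * 3), 6, 3))
  M <- decode_multinomial(Z, p)$M
  expect_equal(rowSums(M), rep(1, 6), tolerance = 1e-9)
  expect_true(all(M > 0 & M < 1))
  # loop oracle for the dense layers + softmax
  fw <- scgcae:::decoder_forward(Z, p)
  i <- 3
  h1 <- pmax(Z[i, ] %*% p$Wd1 + p$bd1, 0)
  h2 <- pmax(h1 %*% p$Wd2 + p$bd2, 0)
  h3 <- pmax(h2 %*% p$Wd3 + p$bd3, 0)
  lg <- drop(h3 %*% p$Wm)
  expect_equal(M[i, ], exp(lg - max(lg)) / sum(exp(lg - max(lg))),
               tolerance = 1e-12)
  # softmax shift invariance: constant shift of one cell's logits
  expect_equal(M[i, ], drop(scgcae:::row_softmax(rbind(lg + 5)) ),
               tolerance = 1e-12)
})

test_that("multinomial loss matches hand values and is minimized at empirical proportions", {
  # one cell, X = (1,1), M = (0.5,0.5): 2 ln 2
  expect_equal(multinomial_loss(matrix(c(1, 1), 1), matrix(c(.5, .5), 1)),
               2 * log(2), tolerance = 1e-12)
  expect_equal(multinomial_loss(matrix(0, 2, 3), matrix(1 / 3, 2, 3)), 0)
  expect_error(multinomial_loss(matrix(c(1, 1), 1), matrix(c(0, 1), 1)))
  # ML closed form: row proportions minimize the loss over the simplex
  set.seed(5)
  X <- matrix(rpois(3 * 6, 4) + 0.5, 3, 6)
  Mstar <- X / rowSums(X)
  Lstar <- multinomial_loss(X, Mstar)
  for (rep in 1:25) {
    R <- matrix(rexp(18), 3, 6); R <- R / rowSums(R)
    expect_gte(multinomial_loss(X, R), Lstar)
  }
})

test_that("backpropagation matches central finite differences", {
  inp <- tiny_pipeline_input(seed = 13, n = 25, g = 40, K = 2, d = 20)
  V <- inp$Xn$values; Abar <- inp$graph$Abar; A <- inp$graph$A
  AX <- Abar %*% V
  for (dec in c("multinomial", "zinb")) {
    p <- gae_init(20, h1 = 6, z_dim = 4, hidden = c(5, 6, 7),
                  decoder = dec, seed = 2)
    lossfun <- function(pp) {
      fw <- scgcae:::gae_forward(pp, Abar, V, AX)
      Lm <- if (dec == "zinb")
        scgcae:::zinb_loss(V, fw$mu, fw$pi, attr(pp, "theta"))
      else multinomial_loss(V, fw$M)
      0.3 * graph_loss(A, decode_graph(fw$Z)) + Lm
    }
    fw <- scgcae:::gae_forward(p, Abar, V, AX)
    gr <- scgcae:::gae_backward(p, fw, Abar, V, A, AX, 0.3, 1.0)
    set.seed(50)
    for (nm in names(gr)) {
      idx <- order(-abs(gr[[nm]]))[1:2]   # probe the largest gradients
      for (i in idx) {
        eps <- 1e-6
        p2 <- p
        p2[[nm]][i] <- p[[nm]][i] + eps; up <- lossfun(p2)
        p2[[nm]][i] <- p[[nm]][i] - eps; dn <- lossfun(p2)
        fd <- (up - dn) / (2 * eps)
        expect_lt(abs(fd - gr[[nm]][i]) /
                    max(1e-8, abs(fd) + abs(gr[[nm]][i])), 1e-4)
      }
    }
  }
})
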