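test_that("correlationMatrix: centering, scaling, errors", {
  set.seed(1)
  x <- rnorm(100)
  Y <- cbind(a = x, b = 2 * x + 5)   # perfectly correlated, shifted
  S <- correlationMatrix(Y, scale = TRUE)
  expect_equal(S["a", "b"], 1)
  expect_equal(diag(S), c(a = 1, b = 1))
  # independent columns: off-diagonals vanish at the sampling rate
  n <- 10000
  Z <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
  S2 <- correlationMatrix(Z, scale = TRUE)
  expect_lt(max(abs(S2[upper.tri(S2)])), 5 / sqrt(n))
  # divisor n, not n - 1
  expect_equal(correlationMatrix(Y)[1, 1], mean((x - mean(x))^2))
  expect_error(correlationMatrix(cbind(a = rep(1, 10), b = rnorm(10)),
                                 scale = TRUE), "a")
})

test_that("glassoPrecision: identity, inverse oracle, decoupled limit", {
  I5 <- diag(5); dimnames(I5) <- list(letters[1:5], letters[1:5])
  expect_lt(max(abs(precisionMatrix(glassoPrecision(I5, 0.001)) - I5)), 1e-3)
  set.seed(2)
  A <- matrix(rnorm(25), 5, 5)
  S <- crossprod(matrix(rnorm(500 * 5), 500, 5) %*% A) / 500
  dimnames(S) <- list(letters[1:5], letters[1:5])
  expect_lt(max(abs(precisionMatrix(glassoPrecision(S, 1e-6)) - solve(S))),
            1e-4)
  omBig <- precisionMatrix(glassoPrecision(S, 1e5))
  expect_equal(max(abs(omBig[upper.tri(omBig)])), 0)
  expect_equal(diag(omBig), 1 / diag(S))
  expect_error(glassoPrecision(S, -1), "nonnegative")
})

test_that("glassoPrecision matches an independent solver at moderate penalty", {
  # frozen oracle: sklearn.covariance.graphical_lasso (tol 1e-10) on this
  # fixture, computed once with an independent implementation
  S <- matrix(c(2, 0.6, 0.3, 0,
                0.6, 1.5, 0.5, 0.2,
                0.3, 0.5, 1.2, 0.4,
                0, 0.2, 0.4, 1), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  ref01 <- rbind(
    c( 0.5466668367, -0.1733334803, -0.0333338877,  0),
    c(-0.1733334803,  0.7866667508, -0.2333331683,  0),
    c(-0.0333338877, -0.2333331683,  0.9842343092, -0.2702702659),
    c( 0,             0,            -0.2702702659,  1.0810810786))
  ref03 <- rbind(
    c( 0.5154639175, -0.1030927832,  0,             0),
    c(-0.1030927832,  0.7024367384, -0.1136363636,  0),
    c( 0,            -0.1136363636,  0.8592755284, -0.0840336134),
    c( 0,             0,            -0.0840336134,  1.0084033613))
  expect_equal(unname(precisionMatrix(glassoPrecision(S, 0.1, tol = 1e-9))),
               ref01, tolerance = 1e-6)
  expect_equal(unname(precisionMatrix(glassoPrecision(S, 0.3, tol = 1e-9))),
               ref03, tolerance = 1e-6)
})

test_that("default glasso penalty switches regime at n = p", {
  expect_equal(defaultGlassoLambda(200, 100), 0.001)
  expect_equal(defaultGlassoLambda(50, 100), sqrt(log(100) / 50))
  expect_equal(defaultGlassoLambda(100, 100), sqrt(log(100) / 100))
  expect_equal(defaultGlassoLambda(50, 100, highdim = "flat"), log(100) / 50)
})

test_that("bottom-up ordering recovers analytic 2- and 3-variable models", {
  # Y2 = 0.8 Y1 + U: Sigma = [[1, .8], [.8, 1.64]], precision diag
  # (1.64, 1.0), minimum at Y2 -> terminal; final order (Y1, Y2)
  Sig2 <- populationCovariance(chainSEM(2))
  om2 <- precisionDiagonal(glassoPrecision(Sig2, 1e-8))
  expect_equal(unname(om2), c(1.64, 1.0), tolerance = 1e-5)
  expect_identical(orderedNodes(bottomUpOrder(S = Sig2, lambda = 1e-8)),
                   c("Y1", "Y2"))
  # chain Y1 -> Y2 -> Y3: first precision diag (1.64, 1.64, 1.0)
  Sig3 <- populationCovariance(chainSEM(3))
  om3 <- precisionDiagonal(glassoPrecision(Sig3, 1e-8))
  expect_equal(unname(om3), c(1.64, 1.64, 1.0), tolerance = 1e-5)
  expect_identical(orderedNodes(bottomUpOrder(S = Sig3, lambda = 1e-8)),
                   c("Y1", "Y2", "Y3"))
})

test_that("layer-mode bottom-up: big eta collapses, eta = 0 is vertex-like", {
  set.seed(5)
  Y <- matrix(rnorm(400 * 5), 400, 5,
              dimnames = list(NULL, paste0("V", 1:5)))
  ld <- bottomUpOrder(Y, granularity = "layer", eta = 100)
  expect_equal(length(nodeLayers(ld)), 1L)
  expect_setequal(nodeLayers(ld)[[1]], paste0("V", 1:5))
  # exact chain input with eta = 0: singleton layers in the vertex order
  Sig <- populationCovariance(chainSEM(4))
  ld0 <- bottomUpOrder(S = Sig, granularity = "layer", eta = 0,
                       lambda = 1e-8)
  expect_identical(nodeLayers(ld0), list("Y1", "Y2", "Y3", "Y4"))
  expect_identical(orderedNodes(ld0),
                   orderedNodes(bottomUpOrder(S = Sig, lambda = 1e-8)))
})

test_that("bottom-up ordering covers every column exactly once (fuzz)", {
  for (s in 1:10) {
    p <- sample(3:8, 1)
    set.seed(s)
    Y <- matrix(rnorm(150 * p), 150, p,
                dimnames = list(NULL, sprintf("g%02d", 1:p)))
    for (gran in c("vertex", "layer")) {
      ord <- bottomUpOrder(Y, granularity = gran, eta = 0.05)
      expect_setequal(orderedNodes(ord), colnames(Y))
      expect_equal(anyDuplicated(orderedNodes(ord)), 0L)
    }
  }
  expect_error(bottomUpOrder(matrix(1:10, ncol = 1,
                                    dimnames = list(NULL, "a"))),
               "two")
})

test_that("adaptive eta: identical halves give zero, noise shrinks with n", {
  set.seed(6)
  A <- matrix(rnorm(80 * 5), 80, 5, dimnames = list(NULL, paste0("V", 1:5)))
  expect_equal(adaptiveEta(rbind(A, A)), 0)
  expect_error(adaptiveEta(A), "n > 100")
  etaBar <- vapply(c(200, 500, 2000), function(n) {
    mean(vapply(1:20, function(s) {
      set.seed(1000 * s + n)
      adaptiveEta(matrix(rnorm(n * 10), n, 10,
                         dimnames = list(NULL, paste0("V", 1:10))))
    }, 0))
  }, 0)
  expect_true(all(etaBar > 0))
  expect_true(etaBar[1] > etaBar[2] && etaBar[2] > etaBar[3])
})

test_that("knowledge ordering delegates and stays self-consistent", {
  expect_identical(nodeLayers(knowledgeOrder(diamondGraph(), "layer")),
                   list("a", c("b", "c"), "d"))
  expect_identical(orderedNodes(knowledgeOrder(chainGraph(), "vertex")),
                   c("a", "b", "c"))
  expect_error(knowledgeOrder(directedGraph(rbind(c("a", "b"),
                                                  c("b", "a"))), "vertex"))
  # flattened TL order is a valid TO for any DAG
  for (s in 1:20) {
    g <- randomDAG(sample(3:12, 1), 0.3, seed = 600 + s)
    expect_equal(
      backwardEdgeRate(g, orderedNodes(knowledgeOrder(g, "layer"))), 0)
  }
})
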