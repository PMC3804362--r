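test_that("constant targets give the constant mapping with zero dual mass", {
  set.seed(41)
  X <- matrix(rnorm(16), 8, 2)
  m <- trainSVR(X, rep(1.5, 8))
  expect_identical(m@dualCoeffs, rep(0, 8))
  expect_equal(m@bias, 1.5)
  p <- predictStage(m, X)
  expect_equal(p$score, rep(1.5, 8))
})

test_that("targets linear in one feature are fit within the tube at large C", {
  set.seed(42)
  x <- matrix(seq(-1, 1, length.out = 14), ncol = 1)
  y <- as.numeric(2 * x + 1)
  m <- trainSVR(x, y, cost = 1000, epsilon = 0.01, standardize = FALSE,
                gamma = 1)
  f <- predictStage(m, x)$score
  expect_lte(max(abs(f - y)), 0.01 + 1e-6)
})

test_that("the dual solution matches an independent QP oracle", {
  set.seed(7)
  n <- 12
  X <- matrix(rnorm(n * 3), n, 3)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(n, sd = 0.3)
  C <- 10; eps <- 0.1; gam <- 1 / 3
  m <- trainSVR(X, y, cost = C, epsilon = eps, gamma = gam,
                standardize = FALSE)
  K <- gaussianKernelMatrix(X, X, gam)
  objPkg <- svrDualObjective(m@dualCoeffs, K, y, eps)
  # oracle: interior-point QP on the printed dual over z = (alpha, alpha*)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-9, 2 * n)
  cvec <- c(eps - y, eps + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), 1)
  sol <- kernlab::ipop(c = cvec, H = H, A = A, b = 0,
                       l = rep(0, 2 * n), u = rep(C, 2 * n), r = 0)
  z <- kernlab::primal(sol)
  objQP <- svrDualObjective(z[1:n] - z[n + 1:n], K, y, eps)
  expect_lt(abs(objPkg - objQP), 1e-5)
})

test_that("every fit satisfies the dual constraints and KKT tube conditions", {
  set.seed(43)
  for (r in 1:5) {
    n <- 10 + r
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rowSums(X) + rnorm(n, sd = 0.2)
    m <- trainSVR(X, y, cost = 5, epsilon = 0.05)
    expect_lt(abs(sum(m@dualCoeffs)), 1e-6)
    expect_lte(max(abs(m@dualCoeffs)), 5 + 1e-8)
    kk <- svrKKTCheck(m)
    expect_lt(kk$maxFreeSVViolation, 1e-4)
  }
})

test_that("prediction is invariant to training-sample order", {
  set.seed(44)
  n <- 15
  X <- matrix(rnorm(n * 2), n, 2)
  y <- X[, 1] + rnorm(n, sd = 0.1)
  m1 <- trainSVR(X, y)
  p <- sample(n)
  m2 <- trainSVR(X[p, ], y[p])
  b <- matrix(rnorm(10), 5, 2)
  expect_equal(predictStage(m1, b)$score, predictStage(m2, b)$score,
               tolerance = 1e-6)
})

test_that("a near-flat kernel drives every prediction to the bias", {
  set.seed(45)
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)          # centered targets
  m <- trainSVR(X, y, gamma = 1e-8, standardize = FALSE)
  p <- predictStage(m, matrix(rnorm(20), 10, 2))$score
  expect_lt(max(abs(p - mean(p))), 0.05 * max(1, diff(range(y))))
})

test_that("hard stages snap to the nearest label", {
  m <- new("SVRModel", dualCoeffs = rep(0, 2), bias = 0, gamma = 1,
           cost = 1, epsilon = 0.1, supportInputs = matrix(0, 2, 1),
           trainTargets = c(0, 0), featureCenter = 0, featureScale = 1)
  for (sc in list(c(-0.4, 0), c(0.49, 0), c(0.51, 1), c(1.2, 1),
                  c(1.51, 2), c(5, 2))) {
    m2 <- m; m2@bias <- sc[1]
    expect_identical(predictStage(m2, 0)$hardStage, as.integer(sc[2]))
  }
})

test_that("nearest-neighbour classification matches the brute-force distance table", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
               c(4, 4), c(5, 4), c(4, 5), c(5, 5))
  labels <- rep(c(0L, 1L), each = 4)
  for (i in seq_len(8)) {
    d <- sqrt(rowSums((pts[-i, , drop = FALSE] -
                       matrix(pts[i, ], 7, 2, byrow = TRUE))^2))
    oracle <- labels[-i][which.min(d)]
    expect_identical(classifyNN(pts[-i, ], labels[-i], pts[i, ]), oracle)
  }
  # single training sample: its label is always returned
  expect_identical(classifyNN(matrix(c(9, 9), 1), 1L, c(0, 0)), 1L)
  # a test point equal to a training point gets that point's label
  expect_identical(classifyNN(pts, labels, pts[6, ]), 1L)
  expect_error(classifyNN(matrix(numeric(0), 0, 2), integer(), c(0, 0)),
               "empty training set")
})
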