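test_that("shape vectors have the documented dimensions", {
  sph <- icosphere(4, radius = 50)          # 2562 vertices
  liver <- standardizeVertexCount(Surface(vertices(sph), faces(sph), "liver"),
                                  1000L)
  spleen <- Surface(vertices(liver) * 0.5 + 100, faces(liver), "spleen")
  xl <- assembleShapeVector(liver)
  expect_identical(length(xl@values), 3000L)
  xj <- assembleShapeVector(liver, spleen)
  expect_identical(length(xj@values), 6000L)
  # round-trip vector -> vertices -> vector
  vlist <- shapeVectorToVertices(xj)
  expect_equal(vlist$liver, vertices(liver))
  expect_equal(vlist$spleen, vertices(spleen))
  back <- assembleShapeVector(Surface(vlist$liver, faces(liver), "liver"),
                              Surface(vlist$spleen, faces(liver), "spleen"))
  expect_identical(back@values, xj@values)
})

test_that("joint assembly rejects mismatched inputs", {
  a <- icosphere(1, organ = "liver")
  b <- icosphere(2, organ = "spleen")
  expect_error(assembleShapeVector(a, b), "vertex count")
  expect_error(assembleShapeVector(a, icosphere(1, organ = "liver")),
               "liver and .* spleen")
})

test_that("identical training shapes give the mean and no modes", {
  x <- ShapeVector(rnorm(30), "liver")
  model <- fitSSM(list(x, x, x, x))
  expect_equal(meanShape(model), x@values)
  expect_identical(nModes(model), 0L)
  expect_error(avcr(model, 1), "no variance")
})

test_that("a two-sample model is the one-mode model forced by the 1/N covariance", {
  set.seed(2)
  m0 <- rnorm(30)
  d <- rnorm(30)
  model <- fitSSM(list(ShapeVector(m0 + d, "liver"),
                       ShapeVector(m0 - d, "liver")))
  expect_equal(meanShape(model), m0)
  expect_identical(nModes(model), 1L)
  v1 <- eigenshapes(model)[, 1]
  expect_lt(min(abs(sum(v1 * d / sqrt(sum(d^2))) - c(-1, 1))), 1e-8)
  expect_equal(eigenvalues(model)[1], sum(d^2), tolerance = 1e-10)
})

test_that("the dual-route fit matches the brute-force covariance oracle", {
  set.seed(3)
  X <- matrix(rnorm(30 * 10), 30, 10)          # D = 30, N = 10 toy set
  model <- fitSSM(X, layout = "liver")
  # oracle: explicitly form S = (1/N) sum (x-m)(x-m)' and eigendecompose
  m <- rowMeans(X)
  Xc <- X - m
  S <- Xc %*% t(Xc) / ncol(X)
  eo <- eigen(S, symmetric = TRUE)
  k <- nModes(model)
  expect_identical(k, 9L)                      # at most N - 1 modes
  expect_lt(max(abs(eigenvalues(model) - eo$values[seq_len(k)])), 1e-8)
  # eigenvectors agree up to sign
  for (j in seq_len(k)) {
    dotj <- abs(sum(eigenshapes(model)[, j] * eo$vectors[, j]))
    expect_lt(abs(dotj - 1), 1e-8)
  }
  # trace conservation: sum of eigenvalues = total variance
  expect_equal(sum(eigenvalues(model)), mean(colSums(Xc^2)),
               tolerance = 1e-8)
})

test_that("projection and reconstruction are exact on the training span", {
  set.seed(4)
  X <- matrix(rnorm(60 * 8), 60, 8)
  model <- fitSSM(X, layout = "liver")
  for (i in c(1, 5, 8)) {
    b <- projectShape(model, X[, i])
    rec <- reconstructShape(model, b)
    relerr <- sqrt(sum((rec@values - X[, i])^2) / sum(X[, i]^2))
    expect_lt(relerr, 1e-6)
  }
  # x = m -> zero coefficients; x = m + 2 v1 -> b = (2, 0, ..., 0)
  b0 <- projectShape(model, meanShape(model))
  expect_lt(max(abs(coefValues(b0))), 1e-10)
  b2 <- projectShape(model, meanShape(model) + 2 * eigenshapes(model)[, 1])
  expect_equal(coefValues(b2)[1], 2, tolerance = 1e-10)
  expect_lt(max(abs(coefValues(b2)[-1])), 1e-10)
  # zero coefficients reconstruct the mean
  expect_equal(reconstructShape(model, numeric(0))@values, meanShape(model))
})

test_that("repeated fits are bit-identical (deterministic sign convention)", {
  set.seed(6)
  X <- matrix(rnorm(30 * 6), 30, 6)
  a <- fitSSM(X, layout = "liver")
  b <- fitSSM(X, layout = "liver")
  expect_identical(eigenshapes(a), eigenshapes(b))
  expect_identical(eigenvalues(a), eigenvalues(b))
})

test_that("joint-model eigenshapes are orthonormal across the concatenation", {
  coh <- smallCohort(nPerStage = c(4, 3, 2), seed = 21, vertices = 42L,
                     permuteVertices = FALSE, maxRotation = 0,
                     maxTranslation = 0)
  sv <- lapply(subjects(coh), function(s)
    assembleShapeVector(s@liver, s@spleen, s@id))
  model <- fitSSM(sv)
  expect_identical(model@layout, "joint")
  V <- eigenshapes(model)
  gram <- crossprod(V)
  expect_lt(max(abs(gram - diag(ncol(V)))), 1e-8)
  # each mode's liver-block plus spleen-block norm is 1
  half <- nrow(V) / 2
  norms <- colSums(V[seq_len(half), , drop = FALSE]^2) +
    colSums(V[-seq_len(half), , drop = FALSE]^2)
  expect_equal(unname(norms), rep(1, ncol(V)), tolerance = 1e-8)
})

test_that("AVCR is the normalized eigenvalue prefix sum", {
  model <- new("SSMModel", mean = numeric(4),
               eigenshapes = diag(4), eigenvalues = c(4, 3, 2, 1),
               nTrain = 5L, layout = "liver", referenceId = "r",
               vertexCount = 1L)
  expect_equal(avcr(model, 2), 0.7)
  expect_equal(avcr(model, 4), 1.0)
  vals <- vapply(1:4, function(k) avcr(model, k), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(avcr(model, 5), "between 1 and")
})

test_that("layout mismatches and bad inputs are rejected", {
  X <- matrix(rnorm(30 * 5), 30, 5)
  model <- fitSSM(X, layout = "liver")
  expect_error(projectShape(model, ShapeVector(rnorm(30), "spleen")),
               "layout mismatch")
  expect_error(fitSSM(X[, 1, drop = FALSE], layout = "liver"),
               "at least two")
  expect_error(fitSSM(list(ShapeVector(rnorm(30), "liver"),
                           ShapeVector(rnorm(33), "liver"))),
               "inconsistent")
})
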