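test_that("uncentered label correlation matches hand-computed values", {
  # parallel vectors
  expect_equal(modeLabelCorrelation(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  # orthogonal vectors
  expect_equal(modeLabelCorrelation(c(1, -1, 0, 0), c(0, 0, 1, 1)), 0.0)
  # hand-checked arithmetic: |3 + 4| / sqrt(2 * 30)
  expect_equal(modeLabelCorrelation(c(1, 2, 3, 4), c(0, 0, 1, 1)),
               7 / sqrt(60), tolerance = 1e-12)
  expect_error(modeLabelCorrelation(c(0, 0, 0), c(0, 1, 1)),
               "undefined correlation")
})

test_that("the correlation is scale- and sign-invariant as printed", {
  set.seed(31)
  for (i in 1:20) {
    b <- rnorm(15)
    r <- rbinom(15, 1, 0.4)
    if (all(r == 0)) r[1] <- 1
    base <- modeLabelCorrelation(b, r)
    expect_equal(modeLabelCorrelation(3.7 * b, r), base, tolerance = 1e-12)
    expect_equal(modeLabelCorrelation(-b, r), base, tolerance = 1e-12)
    expect_equal(modeLabelCorrelation(-b, -r), base, tolerance = 1e-12)
    expect_gte(base, 0); expect_lte(base, 1)
  }
})

test_that("uncentered and Pearson variants differ as documented", {
  b <- c(5, 6, 7, 8)
  r <- c(0, 0, 1, 1)
  expect_equal(modeLabelCorrelation(b, r, centered = TRUE),
               abs(cor(b, r)) * 1, tolerance = 1e-12)
  expect_gt(modeLabelCorrelation(b, r), modeLabelCorrelation(b, r, centered = TRUE) - 1)
  expect_false(isTRUE(all.equal(modeLabelCorrelation(b, r),
                                modeLabelCorrelation(b, r, centered = TRUE))))
})

test_that("correlation ranking finds a label-tracking mode among noise", {
  set.seed(32)
  n <- 30
  labels <- rep(c(0, 1), each = 15)
  B <- matrix(rnorm(n * 8), n, 8)
  B[, 5] <- labels * 2 + rnorm(n, sd = 0.05)
  sel <- selectByCorrelation(B, labels, topK = 4)
  expect_identical(sel[1], 5L)
  # exhaustive verification against direct evaluation
  corr <- vapply(1:8, function(j) modeLabelCorrelation(B[, j], labels),
                 numeric(1))
  expect_identical(as.integer(sel), as.integer(order(-corr, 1:8)[1:4]))
  # permutation invariance: shuffle subjects identically
  p <- sample(n)
  sel2 <- selectByCorrelation(B[p, ], labels[p], topK = 4)
  expect_identical(as.integer(sel2), as.integer(sel))
})

test_that("correlation ranking tie-breaks toward smaller mode indices", {
  labels <- c(0, 1, 1, 0)
  B <- matrix(rep(c(1, 2, 2, 1), 3), 4, 3)  # identical modes
  expect_identical(as.integer(selectByCorrelation(B, labels, topK = 2)),
                   c(1L, 2L))
  expect_identical(as.integer(selectByCorrelation(B, labels, topK = 3)),
                   1:3)
  expect_warning(sel <- selectByCorrelation(B, labels, topK = 5), "clipping")
  expect_identical(length(sel), 3L)
})

test_that("AVCR selection returns the smallest qualifying prefix", {
  model <- new("SSMModel", mean = numeric(4), eigenshapes = diag(4),
               eigenvalues = c(4, 3, 2, 1), nTrain = 5L, layout = "liver",
               referenceId = "r", vertexCount = 1L)
  expect_identical(selectByAvcr(model, threshold = 0.65), 1:2)
  expect_identical(selectByAvcr(model, threshold = 1.0), 1:4)
  expect_identical(selectByAvcr(model, topK = 2), 1:2)
  expect_error(selectByAvcr(model, threshold = 1.5), "threshold")
  # always a prefix
  for (th in c(0.1, 0.4, 0.7, 0.9, 1)) {
    sel <- selectByAvcr(model, threshold = th)
    expect_identical(sel, seq_len(length(sel)))
  }
})

test_that("the product set combines the two criteria", {
  corr <- c(0.1, 0.9, 0.8, 0.2, 0.3, 0.4, 0.95, 0.5, 0.99)
  ms <- combineSelections(1:5, c(2L, 7L, 3L, 9L), corr, finalCount = NULL)
  expect_identical(selectedModes(ms), c(2L, 3L))  # ordered by correlation
  expect_false(ms@fallback)
  ms1 <- combineSelections(1:5, c(2L, 7L, 3L, 9L), corr, finalCount = 1L)
  expect_identical(selectedModes(ms1), 2L)
  # disjoint sets fall back to the best-correlated AVCR mode, with warning
  expect_warning(fb <- combineSelections(1:3, c(7L, 9L), corr), "empty product set")
  expect_true(fb@fallback)
  expect_identical(selectedModes(fb), 2L)
  expect_error(combineSelections(integer(), 1:2, corr), "non-empty")
})

test_that("combined selection recovers the stage-linked mode across replicates", {
  hits <- 0L
  nrep <- 50L
  for (r in seq_len(nrep)) {
    coh <- smallCohort(nPerStage = c(8, 5, 3), seed = 1000L + r,
                       vertices = 42L, permuteVertices = FALSE,
                       maxRotation = 0, maxTranslation = 0)
    labels <- cohortToLabelTable(coh)
    sv <- lapply(subjects(coh), function(s)
      assembleShapeVector(s@liver, s@spleen, s@id))
    model <- fitSSM(sv)
    ms <- suppressWarnings(
      selectModes(model, sv, labels$binaryLabel, finalCount = 1L))
    # ground truth: the mode whose coefficients track the latent stage best
    B <- coefficientMatrix(model, sv)
    truth <- which.max(abs(suppressWarnings(cor(B, labels$stageLabel))))
    if (selectedModes(ms)[1] == truth) hits <- hits + 1L
  }
  expect_gte(hits / nrep, 0.9)
})
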