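# shared fixtures, all built in code

# digital ball of given radius (voxels), unit spacing
makeBallVolume <- function(radius = 10, pad = 3, organ = "liver") {
  d <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  idx <- seq_len(d) - ctr
  g <- array(0L, c(d, d, d))
  r2 <- outer(outer(idx^2, idx^2, "+"), idx^2, "+")
  g[r2 <= radius^2] <- 1L
  LabelVolume(g, organ = organ)
}

makeCubeVolume <- function(side = 8, pad = 2, organ = "liver") {
  d <- side + 2 * pad
  g <- array(0L, c(d, d, d))
  g[pad + seq_len(side), pad + seq_len(side), pad + seq_len(side)] <- 1L
  LabelVolume(g, organ = organ)
}

# an asymmetric organ-like fixture (no rotational symmetry, unlike a sphere)
liverFixture <- function(vertices = 162L, seed = 3) {
  coh <- generateCohort(CohortSpec(nPerStage = c(2, 1, 1), seed = seed,
                                   vertices = vertices,
                                   permuteVertices = FALSE,
                                   maxRotation = 0, maxTranslation = 0,
                                   noiseSd = 0))
  subjects(coh)[[1]]@liver
}

# a small fully-exercised cohort for pipeline tests (cheap vertex count)
smallCohort <- function(nPerStage = c(6, 4, 2), seed = 1, vertices = 42L,
                        ...) {
  generateCohort(CohortSpec(nPerStage = nPerStage, seed = seed,
                            vertices = vertices, ...))
}

# memoised expensive runs shared across test files
.morphostageTestCache <- new.env(parent = emptyenv())

cachedRun <- function(key, expr) {
  if (is.null(.morphostageTestCache[[key]]))
    .morphostageTestCache[[key]] <- force(expr)
  .morphostageTestCache[[key]]
}

# the study-condition cohort: Table-1-style 25/8/2 staged counts, seed 0,
# full nuisance variation (misalignment + permuted vertex order)
defaultCohortRun <- function() {
  cachedRun("defaultRun", {
    coh <- generateCohort(CohortSpec(seed = 0))
    tab <- compareMethods(coh, pipelineConfig())
    list(cohort = coh, table = tab, reports = attr(tab, "reports"))
  })
}
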