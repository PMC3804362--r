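test_that("self-registration returns the identity", {
  s <- liverFixture()
  tf <- registerRigid(s, s)
  expect_lt(max(abs(tf@rotation - diag(3))), 1e-6)
  expect_lt(max(abs(tf@translation)), 1e-6)
})

test_that("a known rigid offset is recovered", {
  s <- liverFixture()
  truth <- RigidTransform(rotationMatrix(c(0, 0, 1), 15 * pi / 180),
                          c(5, -3, 2))
  mov <- applyTransform(s, truth)
  tf <- registerRigid(mov, s, searchAxes = TRUE)
  comp <- composeTransforms(tf, truth)
  expect_lt(max(abs(comp@rotation - diag(3))), 1e-3)
  expect_lt(max(abs(comp@translation)), 1e-3)
})

test_that("random ground-truth transforms are recovered within 1 degree", {
  s <- liverFixture()
  size <- boundingBoxDiagonal(s)
  set.seed(42)
  for (rep in 1:5) {
    ang <- runif(1, 0, 30) * pi / 180
    ax <- rnorm(3)
    tr <- runif(3, -0.2, 0.2) * size
    truth <- RigidTransform(rotationMatrix(ax, ang), tr)
    tf <- registerRigid(applyTransform(s, truth), s, searchAxes = TRUE)
    comp <- composeTransforms(tf, truth)
    expect_lt(morphostage:::rotationAngle(comp@rotation) * 180 / pi, 1)
  }
})

test_that("degenerate (collinear) input is rejected", {
  pts <- cbind(seq_len(10), 0, 0)
  line <- new("Surface", vertices = matrix(as.numeric(pts), ncol = 3),
              faces = matrix(integer(0), 0, 3), organ = "liver")
  ref <- liverFixture()
  expect_error(registerRigid(line, ref), "collinear")
})

test_that("reflections are not representable as rigid transforms", {
  expect_error(RigidTransform(diag(c(-1, 1, 1)), c(0, 0, 0)),
               "det")
})

test_that("organ tags must agree", {
  s <- liverFixture()
  sp <- Surface(vertices(s), faces(s), organ = "spleen")
  expect_error(registerRigid(sp, s), "organ")
})

test_that("applyTransform preserves distances and composes correctly", {
  s <- icosphere(1, radius = 7)
  tf <- RigidTransform(rotationMatrix(c(1, 2, 3), 0.7), c(10, -4, 2))
  moved <- applyTransform(s, tf)
  d0 <- dist(vertices(s))
  d1 <- dist(vertices(moved))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # identity transform leaves the surface unchanged
  expect_equal(vertices(applyTransform(s, RigidTransform())), vertices(s))
  # t then inverse(t) restores the original
  back <- applyTransform(moved, invertTransform(tf))
  expect_lt(max(abs(vertices(back) - vertices(s))), 1e-9)
})

test_that("a 90-degree rotation about z maps (1,0,0) to (0,1,0)", {
  R <- rotationMatrix(c(0, 0, 1), pi / 2)
  expect_equal(as.numeric(R %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
})
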