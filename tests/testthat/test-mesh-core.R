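test_that("empty segmentation is rejected", {
  g <- array(0L, c(8, 8, 8))
  expect_error(extractSurface(LabelVolume(g, organ = "liver")),
               "empty segmentation")
})

test_that("extracted digital ball matches the analytic sphere", {
  vol <- makeBallVolume(radius = 10)
  s <- extractSurface(vol)
  expect_s4_class(s, "Surface")
  expect_identical(organ(s), "liver")
  # analytic oracles: area 4*pi*r^2, volume 4/3*pi*r^3, Euler characteristic 2
  expect_lt(abs(meshArea(s) / (4 * pi * 100) - 1), 0.05)
  expect_lt(abs(meshVolume(s) / (4 / 3 * pi * 1000) - 1), 0.05)
  expect_identical(eulerCharacteristic(s), 2L)
  expect_true(isClosedSurface(s))
})

test_that("a solid cube extracts as a closed genus-0 mesh", {
  s <- extractSurface(makeCubeVolume(side = 8))
  expect_identical(eulerCharacteristic(s), 2L)
  expect_true(isClosedSurface(s))
  # outward orientation: enclosed volume is positive and near 8^3
  expect_gt(meshVolume(s), 0)
})

test_that("disconnected foreground keeps the largest component with a warning", {
  g <- array(0L, c(20, 20, 20))
  g[3:12, 3:12, 3:12] <- 1L   # big block
  g[16:18, 16:18, 16:18] <- 1L  # small distant block
  expect_warning(s <- extractSurface(LabelVolume(g, organ = "liver")),
                 "disconnected")
  # the surviving surface encloses roughly the big block only
  expect_lt(meshVolume(s), 11^3)
  expect_gt(meshVolume(s), 6^3)
})

test_that("vertex-count standardization hits the target exactly", {
  s <- extractSurface(makeBallVolume(radius = 10))
  expect_gt(nrow(vertices(s)), 1000)
  out <- standardizeVertexCount(s, 1000L)
  expect_identical(nrow(vertices(out)), 1000L)
  expect_true(isClosedSurface(out))
  expect_identical(eulerCharacteristic(out), 2L)
  # area preserved within 5%
  expect_lt(abs(meshArea(out) / meshArea(s) - 1), 0.05)
  # Hausdorff deviation within 2% of the bounding-box diagonal
  expect_lt(hausdorffDistance(out, s), 0.02 * boundingBoxDiagonal(s))
})

test_that("standardization is the identity at matching counts and rejects upsampling", {
  s <- icosphere(2)
  expect_identical(standardizeVertexCount(s, nrow(vertices(s))), s)
  expect_error(standardizeVertexCount(s, nrow(vertices(s)) + 1L),
               "upsampling")
  expect_error(standardizeVertexCount(s, 3L), "at least 4")
})

test_that("standardization is deterministic", {
  s <- extractSurface(makeBallVolume(radius = 8))
  a <- standardizeVertexCount(s, 500L)
  b <- standardizeVertexCount(s, 500L)
  expect_identical(vertices(a), vertices(b))
  expect_identical(faces(a), faces(b))
})

test_that("voxelize -> extract round-trips area and volume within 5%", {
  s <- liverFixture(vertices = 642L)
  vol <- voxelizeSurface(s, spacing = c(2.5, 2.5, 2.5))
  s2 <- extractSurface(vol)
  expect_lt(abs(meshVolume(s2) / meshVolume(s) - 1), 0.05)
  expect_lt(abs(meshArea(s2) / meshArea(s) - 1), 0.05)
})
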