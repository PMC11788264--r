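# Single-calcification generation: voxelization, noise, cleaning, rotation,
# sphericity, segmentation.

test_that("sphere voxelization matches the analytic volume and the brute-force center test", {
  m <- makeBaseShape("sphere", c(0.5, 0.5, 0.5), 0.01)
  analytic <- pi / 6 * 50^3
  expect_lt(abs(voxelCount(m) - analytic) / analytic, 0.02)

  # tiny sphere: brute-force center-in-sphere enumeration over the grid
  m2 <- makeBaseShape("sphere", c(0.03, 0.03, 0.03), 0.01)
  expect_equal(voxelCount(m2), oracleSphereCount(0.03, 0.01, 5L))
  expect_equal(voxelCount(m2), 19L)  # frozen from the enumeration oracle

  # one empty pad voxel on every face
  g <- voxelGrid(m)
  expect_false(any(g[1, , ]) || any(g[dim(g)[1], , ]) ||
                 any(g[, 1, ]) || any(g[, , 1]))
})

test_that("base-shape errors: unknown shape, sub-voxel dims, empty teacup", {
  expect_error(makeBaseShape("cone", c(0.5, 0.5, 0.5), 0.01))
  expect_error(makeBaseShape("sphere", c(0.005, 0.005, 0.005), 0.01),
               "smaller than one voxel")
  expect_error(makeBaseShape("teacup", c(0.3, 0.3, 0.3), 0.01,
                             teacupShiftFrac = 0), "empty")
})

test_that("teacup and cylinder solids have the expected gross structure", {
  tc <- makeBaseShape("teacup", c(0.4, 0.4, 0.4), 0.01)
  el <- makeBaseShape("ellipsoid", c(0.4, 0.4, 0.4), 0.01)
  expect_lt(voxelCount(tc), voxelCount(el))  # a piece was carved away
  cy <- makeBaseShape("cylinder", c(0.2, 0.2, 0.4), 0.02)
  # analytic cylinder volume pi r^2 h in voxels
  expect_lt(abs(voxelCount(cy) - pi * 5^2 * 20) / (pi * 5^2 * 20), 0.05)
  rnd <- makeBaseShape("random", c(0.1, 0.1, 0.1), 0.01)
  expect_equal(voxelCount(rnd), 1000L)  # filled cube awaiting noise carving
})

test_that("boundary noise honours its boundary cases and retention rate", {
  m <- makeBaseShape("sphere", c(0.4, 0.4, 0.4), 0.01)
  expect_identical(voxelGrid(applyBoundaryNoise(m, 0, seed = 1)),
                   voxelGrid(m))
  inv <- applyBoundaryNoise(m, 1, seed = 1)
  expect_identical(voxelGrid(inv), !voxelGrid(m))

  noisy <- applyBoundaryNoise(m, 0.3, seed = 42)
  n <- voxelCount(m)
  retained <- sum(voxelGrid(noisy) & voxelGrid(m)) / n
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(retained - 0.7), 3 * se)

  expect_error(applyBoundaryNoise(m, 1.2), "sigma")
  # determinism
  a <- applyBoundaryNoise(m, 0.4, seed = 7)
  b <- applyBoundaryNoise(m, 0.4, seed = 7)
  expect_identical(voxelGrid(a), voxelGrid(b))
})

test_that("cleaning opens, closes, and keeps the largest 26-connected component", {
  g <- array(FALSE, c(12, 12, 12))
  g[2:6, 2:6, 2:6] <- TRUE    # 125 voxels
  g[9:10, 9:10, 9:10] <- TRUE # 8 voxels, disjoint
  out <- cleanModel(VoxelModel3D(g, 0.1))
  # the small cube vanishes (opening + largest-component selection); what
  # survives is a single component inside the big cube's bounding box (the
  # cross element legitimately shaves the cube's corners and edges)
  expect_false(any(voxelGrid(out)[9:10, 9:10, 9:10]))
  expect_gt(voxelCount(out), 0L)
  expect_equal(max(labelComponents(voxelGrid(out))), 1L)
  expect_true(all(which(voxelGrid(out), arr.ind = TRUE) >= 2 &
                    which(voxelGrid(out), arr.ind = TRUE) <= 6))

  # single interior hole is filled by closing
  h <- array(FALSE, c(9, 9, 9))
  h[2:8, 2:8, 2:8] <- TRUE
  h[5, 5, 5] <- FALSE
  out2 <- cleanModel(VoxelModel3D(h, 0.1))
  expect_true(voxelGrid(out2)[5, 5, 5])

  # isolated voxel: hand-evaluated erosion removes it
  s <- array(FALSE, c(5, 5, 5)); s[3, 3, 3] <- TRUE
  expect_identical(oracleDilate(oracleErode(s)), array(FALSE, c(5, 5, 5)))
  expect_equal(voxelCount(cleanModel(VoxelModel3D(s, 0.1))), 0L)
})

test_that("cleaning is idempotent and leaves at most one component", {
  for (seed in 1:3) {
    m <- applyBoundaryNoise(makeBaseShape("sphere", c(0.3, 0.3, 0.3), 0.01),
                            0.4, seed = seed)
    c1 <- cleanModel(m)
    if (voxelCount(c1) > 0L)
      expect_equal(max(labelComponents(voxelGrid(c1))), 1L)
    c2 <- cleanModel(c1)
    expect_identical(voxelGrid(c2), voxelGrid(c1))
  }
})

test_that("rotation: identity, exact 90-degree permutation, volume preservation", {
  g <- array(FALSE, c(4, 3, 2))
  g[1:3, 1, 1] <- TRUE; g[1, 2, 1] <- TRUE  # asymmetric L
  m <- VoxelModel3D(g, 0.1)
  expect_identical(voxelGrid(rotateModel(m, c(0, 0, 0))), g)
  expect_identical(voxelGrid(rotateModel(m, c(0, 0, 90))), oracleRot90z(g))

  s <- makeBaseShape("sphere", c(0.4, 0.4, 0.4), 0.01)
  r <- rotateModel(s, c(0, 0, 45))
  expect_lt(abs(voxelCount(r) - voxelCount(s)) / voxelCount(s), 0.10)
})

test_that("sphericity: exact for spheres, matches independent evaluation otherwise", {
  r <- 0.7
  expect_equal(shapeSphericity(c(r, r, r), "sphere", 4 / 3 * pi * r^3), 1.0,
               tolerance = 1e-12)
  V <- 4 / 3 * pi * 1 * 1 * 2
  expect_equal(shapeSphericity(c(1, 1, 2), "ellipsoid", V),
               oracleSphericity(c(1, 1, 2), V), tolerance = 1e-12)
  expect_equal(round(shapeSphericity(c(1, 1, 2), "ellipsoid", V), 2), 0.93)

  # elliptic cylinder: verbatim surface formula, independently evaluated
  V <- pi * 1 * 1 * 2
  A <- 2 * pi * 1 * 2 + 2 * pi * (1^2 + 2^2) / (2 * 1)
  expect_equal(shapeSphericity(c(1, 1, 1), "elliptic_cylinder", V),
               pi^(1 / 3) * (6 * V)^(2 / 3) / A, tolerance = 1e-12)

  expect_error(shapeSphericity(c(1, 1, 1), "sphere", 0), "volume")
})

test_that("voxelized-sphere sphericity converges to 1 at fine voxel sizes", {
  m <- makeBaseShape("sphere", c(0.5, 0.5, 0.5), 0.01)  # d/voxel = 50
  sph <- modelSphericity(m, "sphere", semiAxesMm = c(0.25, 0.25, 0.25))
  expect_lt(abs(sph - 1), 0.05)
})

test_that("generation is reproducible and respects its size ranges", {
  spec <- list(shape = "ellipsoid", sizeMm = list(c(0.1, 0.1), c(0.15, 0.15),
                                                  c(0.2, 0.2)),
               noise = 0, rotationDeg = FALSE, voxelSizeMm = 0.01)
  a <- generateCalcification(spec, seed = 5)
  b <- generateCalcification(spec, seed = 5)
  expect_identical(voxelGrid(a$model), voxelGrid(b$model))
  expect_equal(a$record$noise_threshold, 0)
  expect_equal(a$record$req_z_mm, 0.2)

  spec2 <- list(shape = "sphere", sizeMm = c(0.1, 0.2), noise = c(0, 0.3),
                rotationDeg = c(0, 360), voxelSizeMm = 0.01)
  set.seed(99)
  for (i in 1:100) {
    g <- generateCalcification(spec2, id = sprintf("c%d", i))
    expect_lte(max(extentMm(g$model)), 0.2 + 2 * 0.01)
  }
})

test_that("generation rejects out-of-bounds tuning parameters", {
  expect_error(generateCalcification(list(shape = "sphere", sizeMm = c(0.5, 2.5),
                                          voxelSizeMm = 0.05)), "0.01-2.00")
  expect_error(generateCalcification(list(shape = "sphere", sizeMm = 0.5,
                                          noise = 1.5, voxelSizeMm = 0.05)),
               "noise")
  expect_error(generateCalcification(list(shape = "sphere", sizeMm = 0.5,
                                          rotationDeg = c(0, 720),
                                          voxelSizeMm = 0.05)), "rotation")
})

test_that("segmentation rescales, thresholds at 0.5 and extracts components", {
  v <- array(0, c(20, 20, 20))
  v[3:5, 3:5, 3:5] <- 1     # 27 voxels
  v[12:15, 12:15, 12:15] <- 1  # 64 voxels
  seg <- segmentCalcifications(v, 0.1)
  expect_length(seg$models, 2L)
  expect_setequal(seg$records$n_voxels, c(27L, 64L))
  expect_true(all(seg$records$shape_label == "segmented"))

  # min-max rescale: {10, 20} -> {0, 1}, only the 20-valued region kept
  v2 <- array(10, c(8, 8, 8)); v2[2:3, 2:3, 2:3] <- 20
  seg2 <- segmentCalcifications(v2, 0.1)
  expect_length(seg2$models, 1L)
  expect_equal(seg2$records$n_voxels, 8L)

  expect_error(segmentCalcifications(array(5, c(4, 4, 4)), 0.1),
               "dynamic range")
})
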