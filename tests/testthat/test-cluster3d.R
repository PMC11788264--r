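# Cluster assembly: placement planning, resizing, OR-composition, presets.

test_that("grid placement is an exact lattice with the requested spacing", {
  p <- planPlacements("grid", c(10, 10, 10), 0.05, 8, minDistanceMm = 1)
  expect_equal(nrow(p), 8L)
  d <- as.matrix(dist(p)); diag(d) <- Inf
  expect_equal(min(d), 1, tolerance = 1e-12)
  # all nearest-neighbour distances exactly the spacing
  expect_true(all(abs(apply(d, 1, min) - 1) < 1e-12))
})

test_that("random placement respects the minimum pairwise distance", {
  p <- planPlacements("random", c(10, 10, 10), 0.05, 20, minDistanceMm = 0.5,
                      seed = 3, marginMm = 0.2)
  expect_equal(nrow(p), 20L)
  d <- as.matrix(dist(p)); diag(d) <- Inf
  expect_gte(min(d), 0.5)   # brute-force over all C(20,2) pairs
  expect_true(all(p >= 0.2 & p <= 9.8))
  # determinism
  p2 <- planPlacements("random", c(10, 10, 10), 0.05, 20, minDistanceMm = 0.5,
                       seed = 3, marginMm = 0.2)
  expect_identical(p, p2)
})

test_that("placement rejects infeasible or invalid requests", {
  expect_error(planPlacements("random", c(0.3, 0.3, 0.3), 0.05, 2,
                              minDistanceMm = 5, maxAttempts = 200L),
               "attempts")
  expect_error(planPlacements("grid", c(1, 1, 1), 0.05, 50, minDistanceMm = 1),
               "cannot hold")
  expect_error(planPlacements("predefined", c(5, 5, 5), 0.05, 1,
                              predefined = matrix(c(9, 1, 1), 1)), "outside")
  pts <- matrix(c(1, 1, 1, 4, 4, 4), 2, byrow = TRUE)
  expect_identical(planPlacements("predefined", c(5, 5, 5), 0.05, 2,
                                  predefined = pts), pts)
})

test_that("resizing scales voxel counts cubically and guards its bounds", {
  m <- makeBaseShape("sphere", c(0.3, 0.3, 0.3), 0.01)
  same <- resizeCalcification(m, max(extentMm(m)))
  expect_lt(abs(voxelCount(same) - voxelCount(m)) / voxelCount(m), 0.12)
  dbl <- resizeCalcification(m, 2 * max(extentMm(m)))
  expect_lt(abs(voxelCount(dbl) - 8 * voxelCount(m)) / (8 * voxelCount(m)),
            0.15)
  tiny <- VoxelModel3D(array(TRUE, c(2, 2, 2)), 0.1)
  expect_error(resizeCalcification(tiny, 0.05), "smaller than one voxel")
})

test_that("assembled clusters invert back to their component calcifications", {
  spec <- ClusterSpec(clusterDimsMm = c(8, 8, 8), voxelSizeMm = 0.05,
                      nCalcs = 20, placementMode = "grid",
                      minDistanceMm = 1.4, source = "generate",
                      calcSpec = list(shape = "sphere", sizeMm = c(0.3, 0.6),
                                      noise = 0, rotationDeg = FALSE))
  cl <- assembleCluster(spec, seed = 7)
  expect_equal(nCalcs(cl), 20L)
  expect_equal(nrow(placements(cl)), 20L)
  expect_equal(clusterRecord(cl)$overlap_voxels, 0L)
  # OR-composition with zero overlap: voxel counts add up exactly
  expect_equal(voxelCount(clusterModel(cl)), sum(placements(cl)$n_voxels))
  seg <- segmentCalcifications(voxelGrid(clusterModel(cl)) * 1, 0.05)
  expect_length(seg$models, 20L)
  expect_setequal(seg$records$n_voxels, placements(cl)$n_voxels)
})

test_that("assembly is bit-reproducible for a fixed seed", {
  spec <- ClusterSpec(clusterDimsMm = c(5, 5, 5), voxelSizeMm = 0.05,
                      nCalcs = c(3, 8), placementMode = "random",
                      minDistanceMm = 0.8, source = "generate",
                      calcSpec = list(shape = "ellipsoid",
                                      sizeMm = c(0.2, 0.5),
                                      noise = c(0, 0.2),
                                      rotationDeg = c(0, 360)))
  a <- assembleCluster(spec, seed = 11)
  b <- assembleCluster(spec, seed = 11)
  expect_identical(voxelGrid(clusterModel(a)), voxelGrid(clusterModel(b)))
  expect_identical(placements(a), placements(b))
})

test_that("a regular spherical grid cluster reproduces the classic 30 mm layout", {
  # cubic 30 x 30 x 30 mm cluster holding 20 grid-placed spherical calcs
  spec <- ClusterSpec(clusterDimsMm = c(30, 30, 30), voxelSizeMm = 0.1,
                      nCalcs = 20, placementMode = "grid",
                      minDistanceMm = 6, source = "generate",
                      calcSpec = list(shape = "sphere", sizeMm = c(1, 1),
                                      noise = 0, rotationDeg = FALSE))
  cl <- assembleCluster(spec, seed = 2)
  seg <- segmentCalcifications(voxelGrid(clusterModel(cl)) * 1, 0.1)
  expect_length(seg$models, 20L)
  d <- as.matrix(dist(placements(cl)[, c("cx_mm", "cy_mm", "cz_mm")]))
  diag(d) <- Inf
  expect_true(all(abs(apply(d, 1, min) - 6) < 1e-9))
})

test_that("database-sourced assembly selects by size/sphericity with resize fallback", {
  set.seed(21)
  recs <- emptyCalcRecords()
  models <- list()
  for (i in 1:6) {
    g <- generateCalcification(list(shape = "sphere",
                                    sizeMm = c(0.3, 0.5), noise = 0,
                                    rotationDeg = FALSE, voxelSizeMm = 0.05),
                               id = sprintf("db_%d", i))
    models[[i]] <- g$model
    recs <- rbind(recs, g$record)
  }
  db <- CalcDatabase(records = recs, models = models)

  spec <- ClusterSpec(clusterDimsMm = c(6, 6, 6), voxelSizeMm = 0.05,
                      nCalcs = 5, placementMode = "random",
                      minDistanceMm = 0.8, source = "database",
                      selectSizeMm = c(0.25, 0.6),
                      selectSphericity = c(0.5, 1.5))
  cl <- assembleCluster(spec, db = db, seed = 4)
  expect_equal(nCalcs(cl), 5L)

  # no candidate in range: resize fallback vs hard error
  specSmall <- ClusterSpec(clusterDimsMm = c(6, 6, 6), voxelSizeMm = 0.05,
                           nCalcs = 2, placementMode = "random",
                           minDistanceMm = 0.8, source = "database",
                           selectSizeMm = c(1.5, 1.8),
                           selectSphericity = c(0.5, 1.5), allowResize = TRUE)
  cl2 <- assembleCluster(specSmall, db = db, seed = 5)
  expect_true(all(placements(cl2)$extent_mm >= 1.3))
  specNo <- specSmall
  specNo@allowResize <- FALSE
  expect_error(assembleCluster(specNo, db = db, seed = 5), "resizing")
  expect_error(assembleCluster(spec, db = NULL, seed = 1), "CalcDatabase")
})

test_that("clinical presets fix the per-category voxel sizes and reject structure-bound types", {
  vox <- c(round = 0.01, punctate = 0.01, milk_of_calcium = 0.01,
           large_rod_like = 0.05, amorphous = 0.005,
           coarse_heterogeneous = 0.01, fine_pleomorphic = 0.01,
           fine_linear = 0.005)
  for (cat_ in names(vox))
    expect_equal(clinicalPreset(cat_)@voxelSizeMm, unname(vox[cat_]))
  expect_error(clinicalPreset("vascular"), "breast structures")
  expect_error(clinicalPreset("skin"), "breast structures")
  expect_error(clinicalPreset("spiculated"), "unknown")
  # presets are editable
  sp <- clinicalPreset("round")
  sp@nCalcs <- c(3, 5)
  expect_s4_class(sp, "ClusterSpec")
})

test_that("ClusterSpec validates tuning bounds up front", {
  expect_error(ClusterSpec(c(0.05, 0.05, 0.05), 0.01), "0.10-100.00")
  expect_error(ClusterSpec(c(5, 5, 5), 0.01, nCalcs = 150), "1-100")
  expect_error(ClusterSpec(c(5, 5, 5), 1.5), "voxel")
  expect_error(ClusterSpec(c(5, 5, 5), 0.01, placementMode = "predefined"),
               "location list")
})
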