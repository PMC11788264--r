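# Assembly of single calcifications into 3D cluster volumes.

#' ClusterSpec: parameters describing a 3D cluster to assemble
#'
#' @slot clusterDimsMm list of three c(min, max) ranges (mm) for the
#'   cluster extent along x, y, z (point values allowed).
#' @slot cubic if TRUE one extent is sampled and used for all three axes.
#' @slot voxelSizeMm isotropic voxel size in mm.
#' @slot nCalcs c(min, max) range (or single value) for the number of
#'   calcifications, 1-100.
#' @slot placementMode \code{"random"}, \code{"grid"} or
#'   \code{"predefined"}.
#' @slot minDistanceMm minimum distance between calcification centres (mm);
#'   the exact lattice spacing in grid mode, a lower bound in random mode.
#' @slot source \code{"generate"} (simulate on the fly) or
#'   \code{"database"} (select stored models by size and sphericity).
#' @slot calcSpec per-calcification generation spec
#'   (see \code{\link{generateCalcification}}).
#' @slot selectSizeMm c(min, max) size selection range for database mode.
#' @slot selectSphericity c(min, max) sphericity selection range.
#' @slot allowResize permit nearest-size resizing when the database holds no
#'   candidate in range.
#' @slot rotationAllowed apply a random rotation to each placed
#'   calcification drawn from a database.
#' @slot predefined matrix of (x, y, z) centre locations in mm for
#'   predefined placement, or NULL.
#' @slot category clinical preset label, or "" for manual specs.
#' @exportClass ClusterSpec
setClass("ClusterSpec",
  representation(clusterDimsMm = "list", cubic = "logical",
                 voxelSizeMm = "numeric", nCalcs = "numeric",
                 placementMode = "character", minDistanceMm = "numeric",
                 source = "character", calcSpec = "list",
                 selectSizeMm = "numeric", selectSphericity = "numeric",
                 allowResize = "logical", rotationAllowed = "logical",
                 predefined = "ANY", category = "character"),
  prototype(cubic = FALSE, allowResize = TRUE, rotationAllowed = FALSE,
            predefined = NULL, category = "",
            selectSizeMm = c(0.01, 2.00), selectSphericity = c(0.01, 2.00)))

#' Create a validated ClusterSpec
#'
#' Ranges are validated against the toolbox tuning bounds before any work
#' starts: cluster extents 0.10-100.00 mm, calcification count 1-100,
#' voxel size in (0, 1] mm, calcification sizes 0.01-2.00 mm.
#'
#' @param clusterDimsMm numeric(3) extents in mm, a single c(min, max)
#'   range (cubic), or a list of three ranges.
#' @param voxelSizeMm voxel size in mm.
#' @param nCalcs number (or c(min, max) range) of calcifications.
#' @param placementMode placement of calcifications in the cluster.
#' @param minDistanceMm minimum centre-to-centre distance in mm.
#' @param source \code{"generate"} or \code{"database"}.
#' @param calcSpec generation spec list (shape, sizeMm, noise, rotationDeg);
#'   its \code{voxelSizeMm} is forced to the cluster's.
#' @param selectSizeMm,selectSphericity database selection ranges.
#' @param allowResize,rotationAllowed flags (see class slots).
#' @param predefined matrix of centres (mm) for predefined mode.
#' @param cubic sample one extent for all three axes.
#' @param category preset label.
#' @return a \linkS4class{ClusterSpec}.
#' @export
ClusterSpec <- function(clusterDimsMm, voxelSizeMm, nCalcs = 10,
                        placementMode = c("random", "grid", "predefined"),
                        minDistanceMm = 0, source = c("generate", "database"),
                        calcSpec = list(), selectSizeMm = c(0.01, 2.00),
                        selectSphericity = c(0.01, 2.00), allowResize = TRUE,
                        rotationAllowed = FALSE, predefined = NULL,
                        cubic = FALSE, category = "") {
  placementMode <- match.arg(placementMode)
  source <- match.arg(source)
  if (is.numeric(clusterDimsMm)) {
    if (length(clusterDimsMm) == 2L) {
      clusterDimsMm <- list(clusterDimsMm)
      cubic <- TRUE
    } else {
      clusterDimsMm <- as.list(rep(clusterDimsMm, length.out = 3L))
    }
  }
  if (cubic && length(clusterDimsMm) == 1L)
    clusterDimsMm <- rep(clusterDimsMm, 3L)
  if (length(clusterDimsMm) != 3L)
    stop("clusterDimsMm must describe three axes (or one cubic range)")
  for (r in clusterDimsMm)
    if (any(r < 0.10 - 1e-12 | r > 100.00 + 1e-12))
      stop("cluster extents must lie within 0.10-100.00 mm")
  if (any(nCalcs < 1 | nCalcs > 100))
    stop("number of calcifications must lie within 1-100")
  if (voxelSizeMm <= 0 || voxelSizeMm > 1)
    stop("voxel size must lie within (0, 1] mm")
  if (minDistanceMm < 0) stop("minDistanceMm must be >= 0")
  if (placementMode == "predefined" && is.null(predefined))
    stop("predefined placement requires a location list")
  if (!is.null(predefined)) predefined <- as.matrix(predefined)
  calcSpec$voxelSizeMm <- voxelSizeMm
  new("ClusterSpec", clusterDimsMm = clusterDimsMm, cubic = cubic,
      voxelSizeMm = voxelSizeMm, nCalcs = as.numeric(nCalcs),
      placementMode = placementMode, minDistanceMm = minDistanceMm,
      source = source, calcSpec = calcSpec,
      selectSizeMm = as.numeric(selectSizeMm),
      selectSphericity = as.numeric(selectSphericity),
      allowResize = allowResize, rotationAllowed = rotationAllowed,
      predefined = predefined, category = category)
}

#' Plan calcification centre locations inside a cluster volume
#'
#' Random mode rejection-samples centres with pairwise distances >=
#' \code{minDistanceMm}; grid mode builds a regular lattice with spacing
#' exactly \code{minDistanceMm}, centred in the volume, and returns the
#' first \code{n} lattice points in raster order (x fastest); predefined
#' mode echoes a validated location list.
#'
#' @param mode \code{"random"}, \code{"grid"} or \code{"predefined"}.
#' @param clusterDimsMm numeric(3) cluster extents in mm.
#' @param voxelSizeMm voxel size in mm (used only for containment checks).
#' @param n number of centres.
#' @param minDistanceMm minimum centre distance in mm.
#' @param predefined matrix of centres (mm) for predefined mode.
#' @param seed optional RNG seed.
#' @param marginMm keep centres at least this far from every face (so that
#'   calcifications of that half-extent stay fully contained).
#' @param maxAttempts rejection-sampling cap for random mode.
#' @return an n x 3 matrix of centres in mm.
#' @export
planPlacements <- function(mode, clusterDimsMm, voxelSizeMm, n,
                           minDistanceMm = 0, predefined = NULL, seed = NULL,
                           marginMm = 0, maxAttempts = NULL) {
  mode <- match.arg(mode, c("random", "grid", "predefined"))
  checkSeed(seed)
  dims <- rep(as.numeric(clusterDimsMm), length.out = 3L)
  lo <- rep(marginMm, 3L)
  hi <- dims - marginMm
  if (any(hi < lo))
    stop("cluster too small to contain calcifications of this size")
  if (mode == "predefined") {
    if (is.null(predefined)) stop("predefined mode requires a location list")
    pts <- as.matrix(predefined)
    if (ncol(pts) != 3L) stop("predefined locations must be (x, y, z) in mm")
    if (nrow(pts) < n) stop("fewer predefined locations than calcifications")
    pts <- pts[seq_len(n), , drop = FALSE]
    out <- t(pts) < lo | t(pts) > hi
    if (any(out))
      stop("predefined location outside the (margin-inset) cluster volume")
    return(unname(pts))
  }
  if (mode == "grid") {
    if (minDistanceMm <= 0) stop("grid mode requires a positive spacing")
    m <- floor((hi - lo) / minDistanceMm) + 1
    if (prod(m) < n)
      stop(sprintf("grid of %d x %d x %d points cannot hold %d calcifications",
                   m[1], m[2], m[3], n))
    axes <- lapply(1:3, function(k)
      dims[k] / 2 + (seq_len(m[k]) - (m[k] + 1) / 2) * minDistanceMm)
    pts <- as.matrix(expand.grid(axes))  # x fastest: raster order
    return(unname(pts[seq_len(n), , drop = FALSE]))
  }
  # random
  if (is.null(maxAttempts)) maxAttempts <- 10000L + 500L * n
  pts <- matrix(NA_real_, n, 3L)
  got <- 0L
  for (att in seq_len(maxAttempts)) {
    cand <- lo + stats::runif(3) * (hi - lo)
    if (got > 0L && minDistanceMm > 0) {
      d2 <- colSums((t(pts[seq_len(got), , drop = FALSE]) - cand)^2)
      if (any(d2 < minDistanceMm^2)) next
    }
    got <- got + 1L
    pts[got, ] <- cand
    if (got == n) return(unname(pts))
  }
  stop(sprintf(
    "could not place %d centres at min distance %g mm after %d attempts",
    n, minDistanceMm, maxAttempts))
}

#' Resize a calcification model to a target extent
#'
#' Nearest-neighbour isotropic zoom so that the largest occupied
#' bounding-box extent equals \code{targetExtentMm} at the model's voxel
#' size; the result is re-binarized.
#'
#' @param model a \linkS4class{VoxelModel3D}.
#' @param targetExtentMm target largest extent in mm (>= one voxel).
#' @param voxelSizeMm optional new voxel size (defaults to the model's);
#'   use this to resample database models onto a cluster's voxel grid.
#' @return the resized \linkS4class{VoxelModel3D}.
#' @export
resizeCalcification <- function(model, targetExtentMm,
                                voxelSizeMm = voxelSize(model)) {
  stopifnot(is(model, "VoxelModel3D"))
  if (targetExtentMm < voxelSizeMm)
    stop("target extent is smaller than one voxel")
  g <- cropToBoundingBox(model@grid)
  d <- dim(g)
  targetVox <- mmToVoxels(targetExtentMm, voxelSizeMm)
  f <- targetVox / max(d)
  nd <- pmax(1L, as.integer(round(d * f)))
  idx <- lapply(1:3, function(k)
    pmin(d[k], pmax(1L, as.integer(ceiling((seq_len(nd[k]) - 0.5) / f)))))
  out <- g[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (!any(out)) stop("resizing produced an empty model")
  VoxelModel3D(padArray(out, 1L), voxelSizeMm)
}

selectFromDatabase <- function(db, sizeRange, sphRange, allowResize) {
  rec <- db@records
  if (nrow(rec) == 0L) stop("calcification database is empty")
  size <- pmax(rec$ext_x_mm, rec$ext_y_mm, rec$ext_z_mm)
  ok <- size >= sizeRange[1] & size <= sizeRange[2] &
    rec$sphericity_value >= sphRange[1] & rec$sphericity_value <= sphRange[2]
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    i <- sample(which(ok), 1L)
    return(list(model = db@models[[i]], record = rec[i, , drop = FALSE],
                resized = FALSE))
  }
  if (!allowResize)
    stop("no database calcification within the size/sphericity ranges ",
         "and resizing is disallowed")
  target <- stats::runif(1, sizeRange[1], sizeRange[2])
  i <- which.min(abs(size - mean(sizeRange)))
  m <- resizeCalcification(db@models[[i]], target)
  r <- rec[i, , drop = FALSE]
  r$ext_x_mm <- extentMm(m)[1]; r$ext_y_mm <- extentMm(m)[2]
  r$ext_z_mm <- extentMm(m)[3]; r$n_voxels <- voxelCount(m)
  list(model = m, record = r, resized = TRUE)
}

#' Assemble a 3D microcalcification cluster
#'
#' Places \code{nCalcs} calcifications (simulated on the fly or selected
#' from a database by size and sphericity) at planned centres by voxel-wise
#' OR.  Placements guarantee full containment -- calcifications are never
#' cropped; voxel-level overlap of neighbouring calcifications is tolerated
#' and logged in the cluster record.
#'
#' @param spec a \linkS4class{ClusterSpec}.
#' @param db a \linkS4class{CalcDatabase} (required when
#'   \code{source = "database"}).
#' @param seed optional RNG seed; the whole assembly is bit-reproducible
#'   given the seed.
#' @param id cluster identifier used in records.
#' @return a \linkS4class{Cluster3D}.
#' @export
assembleCluster <- function(spec, db = NULL, seed = NULL, id = "cluster_1") {
  stopifnot(is(spec, "ClusterSpec"))
  checkSeed(seed)
  if (spec@source == "database" && is.null(db))
    stop("source = 'database' requires a CalcDatabase")
  dims <- if (spec@cubic) rep(sampleRange(spec@clusterDimsMm[[1]]), 3L) else
    vapply(spec@clusterDimsMm, sampleRange, numeric(1))
  n <- if (length(spec@nCalcs) > 1L)
    sample(seq.int(spec@nCalcs[1], spec@nCalcs[2]), 1L) else
    as.integer(spec@nCalcs)
  vs <- spec@voxelSizeMm

  calcs <- vector("list", n)
  records <- emptyCalcRecords()
  for (i in seq_len(n)) {
    if (spec@source == "generate") {
      cs <- spec@calcSpec
      gen <- generateCalcification(cs, id = sprintf("%s_calc_%d", id, i))
      calcs[[i]] <- gen$model
      records <- rbind(records, gen$record)
    } else {
      sel <- selectFromDatabase(db, spec@selectSizeMm, spec@selectSphericity,
                                spec@allowResize)
      m <- sel$model
      if (abs(voxelSize(m) - vs) > 1e-12)
        m <- resizeCalcification(m, max(extentMm(m)), voxelSizeMm = vs)
      if (spec@rotationAllowed)
        m <- rotateModel(m, stats::runif(3, 0, 360))
      calcs[[i]] <- m
      r <- sel$record
      r$id <- sprintf("%s_calc_%d", id, i)
      records <- rbind(records, r)
    }
  }

  halfExt <- vapply(calcs, function(m) max(extentMm(m)) / 2, numeric(1))
  margin <- max(halfExt) + vs  # one voxel of slack for index rounding
  centers <- planPlacements(spec@placementMode, dims, vs, n,
                            minDistanceMm = spec@minDistanceMm,
                            predefined = spec@predefined, marginMm = margin)

  gd <- vapply(dims, mmToVoxels, integer(1), voxelSize = vs)
  grid <- array(FALSE, gd)
  overlap <- 0L
  plc <- data.frame(id = character(n), cx_mm = numeric(n), cy_mm = numeric(n),
                    cz_mm = numeric(n), cx_vox = integer(n),
                    cy_vox = integer(n), cz_vox = integer(n),
                    extent_mm = numeric(n), n_voxels = integer(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sub <- cropToBoundingBox(calcs[[i]]@grid)
    bd <- dim(sub)
    ctr <- pmin(gd, pmax(1L, as.integer(floor(centers[i, ] / vs)) + 1L))
    start <- ctr - as.integer(floor(bd / 2))
    # containment: shift minimally if rounding pushed the box over an edge
    start <- pmax(1L, pmin(start, gd - bd + 1L))
    if (any(start < 1L) || any(start + bd - 1L > gd))
      stop("calcification does not fit inside the cluster volume")
    ix <- seq.int(start[1], start[1] + bd[1] - 1L)
    iy <- seq.int(start[2], start[2] + bd[2] - 1L)
    iz <- seq.int(start[3], start[3] + bd[3] - 1L)
    before <- grid[ix, iy, iz]
    overlap <- overlap + sum(before & sub)
    grid[ix, iy, iz] <- before | sub
    plc$id[i] <- sprintf("%s_calc_%d", id, i)
    plc[i, c("cx_mm", "cy_mm", "cz_mm")] <- centers[i, ]
    plc[i, c("cx_vox", "cy_vox", "cz_vox")] <- ctr
    plc$extent_mm[i] <- max(extentMm(calcs[[i]]))
    plc$n_voxels[i] <- voxelCount(calcs[[i]])
  }
  rec <- list(id = id, cluster_dims_mm = dims, voxel_size_mm = vs,
              n_calcs = n, placement_mode = spec@placementMode,
              min_distance_mm = spec@minDistanceMm,
              overlap_voxels = overlap, category = spec@category,
              calc_records = records)
  new("Cluster3D", model = VoxelModel3D(grid, vs), placements = plc,
      record = rec)
}

#' One-row cluster metadata record
#'
#' @param cluster a \linkS4class{Cluster3D}.
#' @return one-row data.frame for the cluster metadata table.
#' @export
clusterRecordRow <- function(cluster) {
  r <- cluster@record
  data.frame(id = r$id, dim_x_mm = r$cluster_dims_mm[1],
             dim_y_mm = r$cluster_dims_mm[2], dim_z_mm = r$cluster_dims_mm[3],
             voxel_size_mm = r$voxel_size_mm, n_calcs = r$n_calcs,
             placement_mode = r$placement_mode,
             min_distance_mm = r$min_distance_mm,
             overlap_voxels = r$overlap_voxels, category = r$category,
             stringsAsFactors = FALSE)
}

BIRADS_CATEGORIES <- c("round", "punctate", "milk_of_calcium",
                       "large_rod_like", "amorphous", "coarse_heterogeneous",
                       "fine_pleomorphic", "fine_linear")

BIRADS_EXCLUDED <- c("vascular", "skin", "suture")

# Editable preset defaults.  Voxel sizes follow the per-category values the
# method prescribes; all other numbers are package defaults chosen from the
# published benign example (spheres 0.09-0.6 mm, 8-25 per cluster, cubic
# clusters 2.25-6.00 mm) where applicable and otherwise from conservative
# clinically styled values.  Users can edit the returned spec freely.
biradsPresetTable <- function() {
  list(
    round = list(voxel = 0.01, shape = "sphere",
                 size = list(c(0.09, 0.60)), noise = c(0, 0.05),
                 rot = FALSE, cluster = c(2.25, 6.00), n = c(8, 25),
                 minDist = 0.20),
    punctate = list(voxel = 0.01, shape = "sphere",
                    size = list(c(0.09, 0.45)), noise = c(0, 0.05),
                    rot = FALSE, cluster = c(2.25, 5.00), n = c(8, 25),
                    minDist = 0.15),
    milk_of_calcium = list(voxel = 0.01, shape = "teacup",
                           size = list(c(0.20, 0.80)), noise = c(0.02, 0.10),
                           rot = c(0, 360), cluster = c(3.00, 6.00),
                           n = c(5, 15), minDist = 0.30),
    large_rod_like = list(voxel = 0.05, shape = "cylinder",
                          size = list(c(0.30, 0.50), c(0.30, 0.50),
                                      c(1.00, 2.00)),
                          noise = c(0, 0.10), rot = c(0, 360),
                          cluster = c(8.00, 15.00), n = c(3, 8),
                          minDist = 2.00),
    amorphous = list(voxel = 0.005, shape = "random",
                     size = list(c(0.06, 0.20)), noise = c(0.35, 0.55),
                     rot = FALSE, cluster = c(1.50, 3.00), n = c(15, 40),
                     minDist = 0.10),
    coarse_heterogeneous = list(voxel = 0.01, shape = "random",
                                size = list(c(0.50, 1.00)),
                                noise = c(0.25, 0.45), rot = c(0, 360),
                                cluster = c(3.00, 6.00), n = c(5, 15),
                                minDist = 0.50),
    fine_pleomorphic = list(voxel = 0.01, shape = "random",
                            size = list(c(0.10, 0.80)),
                            noise = c(0.30, 0.50), rot = c(0, 360),
                            cluster = c(3.00, 6.00), n = c(10, 30),
                            minDist = 0.15),
    fine_linear = list(voxel = 0.005, shape = "ellipsoid",
                       size = list(c(0.06, 0.12), c(0.06, 0.12),
                                   c(0.30, 0.80)),
                       noise = c(0.10, 0.30), rot = c(0, 30),
                       cluster = c(2.00, 3.00), n = c(10, 20),
                       minDist = 0.12))
}

#' Clinical (BI-RADS style) cluster preset
#'
#' Returns an editable \linkS4class{ClusterSpec} for one of the eight
#' implemented calcification morphologies: four typically benign (round,
#' punctate, milk of calcium, large rod-like) and four of suspicious
#' morphology (amorphous, coarse heterogeneous, fine pleomorphic, fine
#' linear).  The voxel size is fixed per category (0.01 mm for round,
#' punctate, milk of calcium, fine pleomorphic and coarse heterogeneous;
#' 0.05 mm for large rod-like; 0.005 mm for amorphous and fine linear);
#' the remaining defaults are documented, user-overridable package choices.
#' Morphologies tied to existing breast structures (vascular, skin, suture)
#' are rejected by design, since the 3D models carry no surrounding tissue.
#'
#' @param category one of the eight implemented morphology labels.
#' @return an editable \linkS4class{ClusterSpec}.
#' @examples
#' spec <- clinicalPreset("round")
#' spec@voxelSizeMm
#' @export
clinicalPreset <- function(category) {
  if (category %in% BIRADS_EXCLUDED)
    stop(sprintf(paste0("category '%s' depends on existing breast structures",
                        " and is not included in the 3D models"), category))
  if (!category %in% BIRADS_CATEGORIES)
    stop(sprintf("unknown category '%s'; supported: %s", category,
                 paste(BIRADS_CATEGORIES, collapse = ", ")))
  p <- biradsPresetTable()[[category]]
  ClusterSpec(clusterDimsMm = p$cluster, voxelSizeMm = p$voxel,
              nCalcs = p$n, placementMode = "random",
              minDistanceMm = p$minDist, source = "generate",
              calcSpec = list(shape = p$shape, sizeMm = p$size,
                              noise = p$noise, rotationDeg = p$rot,
                              voxelSizeMm = p$voxel),
              cubic = TRUE, category = category)
}
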